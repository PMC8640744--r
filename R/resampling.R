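# Library-size versus sequencing-read trade-off simulator. Raw deep
# mutational scanning data are per-variant read counts in an input
# (pre-screening) and a selected (post-screening) pool; functional scores are
# wild-type-normalized log ratios of those counts. Resampling the counts at
# different library sizes and read budgets, retraining a model on each
# resampled dataset, and evaluating against non-resampled scores traces how
# data quality limits what a supervised model can learn.

#' Construct a read-count table
#'
#' @param variant Character vector of canonical substitution strings
#'   (`""` = wild type); must be unique.
#' @param count_input,count_selected Nonnegative integer read counts per
#'   variant in the input (pre-screening) and selected (post-screening) pools.
#' @return An object of class `read_count_table` (a validated data.frame).
#' @export
count_table <- function(variant, count_input, count_selected) {
  stopifnot(is.character(variant),
            length(variant) == length(count_input),
            length(variant) == length(count_selected))
  if (anyDuplicated(variant)) stop("variants must be unique")
  ci <- as.numeric(count_input)
  cs <- as.numeric(count_selected)
  if (any(ci < 0 | cs < 0 | ci != round(ci) | cs != round(cs)))
    stop("counts must be nonnegative integers")
  structure(data.frame(variant = variant, count_input = ci,
                       count_selected = cs, stringsAsFactors = FALSE),
            class = c("read_count_table", "data.frame"))
}

#' Read / write read-count tables as TSV
#'
#' Columns: `variant`, `count_input`, `count_selected`.
#'
#' @param path File path.
#' @return For `read_counts`, a `read_count_table`.
#' @export
read_counts <- function(path) {
  need <- c("variant", "count_input", "count_selected")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!all(need %in% header))
    stop("count file must have columns ", paste(need, collapse = ", "))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(variant = "character"),
                           na.strings = NULL)
  count_table(tab$variant, tab$count_input, tab$count_selected)
}

#' @rdname read_counts
#' @param t A `read_count_table`.
#' @export
write_counts <- function(t, path) {
  stopifnot(inherits(t, "read_count_table"))
  utils::write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter variants by read count
#'
#' Keeps variants with at least `min_reads` reads in *both* the input and the
#' selected pool. `min_reads = 1` removes variants with zero reads in either
#' pool; `min_reads = 5` reproduces the common five-read quality filter.
#'
#' @param t A `read_count_table`.
#' @param min_reads Minimum reads required in each pool.
#' @return The filtered `read_count_table`.
#' @export
filter_counts <- function(t, min_reads) {
  stopifnot(inherits(t, "read_count_table"), min_reads >= 0)
  keep <- t$count_input >= min_reads & t$count_selected >= min_reads
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wild-type-normalized log-ratio enrichment scores
#'
#' For each variant v,
#' `score(v) = ln((sel_v + 0.5) / (inp_v + 0.5)) - ln((sel_wt + 0.5) / (inp_wt + 0.5))`,
#' the natural-log enrichment ratio with 0.5 pseudocounts, normalized so the
#' wild type scores exactly 0. This is the standard log-ratio scoring form
#' for selection experiments (the pseudocount keeps zero counts finite).
#'
#' @param t A `read_count_table`.
#' @param wt_id Variant string identifying the wild type (default `""`).
#' @return A data.frame with columns `variant` and `score`.
#' @export
enrichment_score <- function(t, wt_id = "") {
  stopifnot(inherits(t, "read_count_table"))
  w <- which(t$variant == wt_id)
  if (length(w) != 1L)
    stop("wild type ('", wt_id, "') missing from the count table")
  lr <- log((t$count_selected + 0.5) / (t$count_input + 0.5))
  data.frame(variant = t$variant, score = lr - lr[w],
             stringsAsFactors = FALSE)
}

#' Resample a read-count dataset at a given library size and read budget
#'
#' Draws a library of `library_size` variants uniformly without replacement
#' from the base table (plus any `include` variants, e.g. the wild type),
#' splits `total_reads` between the input and selected pools according to the
#' base dataset's read fractions (deterministic rounding, so the total is
#' conserved exactly), and samples each pool's counts from a multinomial with
#' probabilities proportional to the base counts restricted to the library.
#'
#' @param base A `read_count_table` (typically pre-filtered to positive
#'   counts).
#' @param library_size Number of distinct variants screened.
#' @param total_reads Total sequencing reads across both pools.
#' @param seed Integer seed.
#' @param include Character vector of variant strings always added to the
#'   library (not counted against `library_size` unless sampled anyway).
#' @return A `read_count_table` over the library (zero-count rows retained);
#'   its counts sum to `total_reads` exactly.
#' @export
resample_dataset <- function(base, library_size, total_reads, seed = 1L,
                             include = NULL) {
  stopifnot(inherits(base, "read_count_table"),
            library_size >= 1L, library_size <= nrow(base),
            total_reads >= 1L)
  lib_idx <- withr::with_seed(seed,
                              sample.int(nrow(base), library_size))
  if (!is.null(include)) {
    extra <- match(setdiff(include, base$variant[lib_idx]), base$variant)
    extra <- extra[!is.na(extra)]
    lib_idx <- c(lib_idx, extra)
  }
  lib <- base[lib_idx, , drop = FALSE]
  if (nrow(lib) == 0L) stop("empty library")
  frac_input <- sum(base$count_input) /
    (sum(base$count_input) + sum(base$count_selected))
  n_input <- round(total_reads * frac_input)
  n_selected <- total_reads - n_input
  draw <- function(n, wts) {
    if (n == 0L) return(numeric(nrow(lib)))
    if (all(wts == 0)) stop("library has zero total reads in one pool")
    as.numeric(stats::rmultinom(1L, n, wts))
  }
  counts <- withr::with_seed(seed + 1L, {
    list(inp = draw(n_input, lib$count_input),
         sel = draw(n_selected, lib$count_selected))
  })
  count_table(lib$variant, counts$inp, counts$sel)
}

#' Run the library-size / read-budget resampling grid
#'
#' For every combination of library size and total read budget, generates
#' `replicates` resampled datasets (test-set variants are removed from the
#' base first, so they can never enter a training library), scores them with
#' [enrichment_score()] after dropping variants with zero reads in either
#' pool, trains a model on an 80/20 train/tune split of each, and evaluates
#' the mean test-set Pearson correlation against the non-resampled ("true")
#' scores. Cells in which any replicate ends up with fewer than
#' `min_variants` scored variants are marked excluded.
#'
#' @param base A `read_count_table` for the full dataset.
#' @param test A `dms_dataset` of held-out variants with non-resampled scores.
#' @param wt A [wild_type()] object.
#' @param proj A `property_projection`.
#' @param spec A [model_spec()] used (rebuilt per replicate) for training.
#' @param library_sizes,read_budgets Integer vectors defining the grid.
#' @param replicates Resampled datasets per cell (default 5).
#' @param min_variants Minimum scored variants per replicate (default 25).
#' @param config A [training_config()].
#' @param wt_id Wild-type variant string in `base` (default `""`).
#' @param seed Integer seed.
#' @return A data.frame with one row per grid cell: `library_size`,
#'   `total_reads`, `mean_pearson` (NA when excluded), `excluded`,
#'   `min_scored_variants` and `n_datasets` (total resampled datasets built).
#' @export
run_grid <- function(base, test, wt, proj, spec,
                     library_sizes, read_budgets, replicates = 5L,
                     min_variants = 25L, config = training_config(),
                     wt_id = "", seed = 1L) {
  stopifnot(inherits(base, "read_count_table"), inherits(test, "dms_dataset"))
  pool <- base[!(base$variant %in% setdiff(test$data$variant, wt_id)), ,
               drop = FALSE]
  class(pool) <- class(base)
  X_test <- encode_variants(test, wt, proj)
  y_test <- test$data$score
  grid <- expand.grid(library_size = library_sizes,
                      total_reads = read_budgets)
  grid$mean_pearson <- NA_real_
  grid$excluded <- FALSE
  grid$min_scored_variants <- NA_integer_
  n_datasets <- 0L
  for (gi in seq_len(nrow(grid))) {
    lib_size <- min(grid$library_size[gi], nrow(pool))
    scored_counts <- integer(replicates)
    pearsons <- rep(NA_real_, replicates)
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      rs <- resample_dataset(pool, lib_size, grid$total_reads[gi],
                             seed = seed + 1000L * gi + r, include = wt_id)
      n_datasets <- n_datasets + 1L
      observed <- filter_counts(rs, 1L)
      scored_counts[r] <- nrow(observed)
      reps[[r]] <- observed
    }
    grid$min_scored_variants[gi] <- min(scored_counts)
    if (any(scored_counts < min_variants) ||
        any(vapply(reps, function(o) !wt_id %in% o$variant, logical(1)))) {
      grid$excluded[gi] <- TRUE
      next
    }
    for (r in seq_len(replicates)) {
      scores <- enrichment_score(reps[[r]], wt_id)
      ds <- dms_dataset(wt, scores$variant, scores$score)
      n <- n_variants(ds)
      n_tune <- max(1L, floor(0.2 * n))
      perm <- withr::with_seed(seed + 1000L * gi + r, sample.int(n))
      tune_idx <- perm[seq_len(n_tune)]
      train_idx <- perm[-seq_len(n_tune)]
      X <- encode_variants(ds, wt, proj)
      m <- build_model(spec, wt$length, dim(X)[3])
      m <- train_model(m,
                       X[train_idx, , , drop = FALSE], ds$data$score[train_idx],
                       X[tune_idx, , , drop = FALSE], ds$data$score[tune_idx],
                       config)
      pred <- predict(m, X_test)
      pearsons[r] <- if (stats::sd(pred) == 0) NA_real_
                     else stats::cor(pred, y_test)
    }
    grid$mean_pearson[gi] <- mean(pearsons)
  }
  attr(grid, "n_datasets") <- n_datasets
  grid
}
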