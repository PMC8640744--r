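# Variant encoding: per-residue 21-letter one-hot concatenated with a
# low-dimensional PCA projection of amino-acid physicochemical properties.
# With 20 amino acids the centered property matrix has rank <= 19, so 19
# components always capture all of the variance.

#' Read an amino-acid property matrix from CSV
#'
#' The expected layout mirrors AAindex-style tables: one row per standard
#' amino acid, an `aa` column with the one-letter code, and one numeric column
#' per property. The packaged file
#' `system.file("extdata", "aa_properties_synthetic.csv", package = "dms2func")`
#' is a synthetic stand-in with the same shape as a curated property database.
#'
#' @param path CSV file path.
#' @return A numeric matrix with 20 rows (rownames = amino-acid letters,
#'   alphabet order) and one column per property.
#' @export
read_property_matrix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"aa" %in% names(tab)) stop("property CSV must have an 'aa' column")
  if (!setequal(tab$aa, AA20))
    stop("property CSV must contain exactly the 20 standard amino acids")
  m <- as.matrix(tab[, setdiff(names(tab), "aa"), drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("property values must be finite numerics")
  rownames(m) <- tab$aa
  m <- m[AA20, , drop = FALSE]
  if (ncol(m) < 1L) stop("property matrix needs at least one property column")
  m
}

#' Fit a PCA projection of amino-acid properties
#'
#' Properties are standardized (zero mean, unit variance per column;
#' zero-variance columns are dropped with a warning) and projected onto the
#' top `d` principal components. Because only 20 amino-acid rows exist, the
#' centered matrix has rank at most 19 and `d = 19` captures 100% of the
#' variance. The stop symbol `"*"`, which has no physicochemical properties,
#' is assigned the zero vector. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so results are
#' reproducible across platforms.
#'
#' @param props 20-row numeric property matrix from [read_property_matrix()].
#' @param d Number of components to keep (default 19).
#' @return An object of class `property_projection`: list with `scores`
#'   (21 x d matrix, rows AA letters then `"*"`), `d`, `explained` (fraction of
#'   variance per kept component), `cum_explained`, `center`, `scale` and
#'   `rotation` for the retained property columns.
#' @export
fit_property_projection <- function(props, d = 19L) {
  stopifnot(is.matrix(props), nrow(props) == 20L)
  d <- as.integer(d)
  sds <- apply(props, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance property column(s)")
    props <- props[, sds > 0, drop = FALSE]
  }
  if (ncol(props) < 1L)
    stop("all property columns have zero variance; nothing to project")
  max_d <- min(19L, ncol(props))
  if (d < 1L || d > max_d)
    stop("d must be in [1, ", max_d, "] for this property matrix")
  pc <- stats::prcomp(props, center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(d)) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  scaled <- scale(props, center = pc$center, scale = pc$scale)
  scores20 <- scaled %*% rot
  scores <- rbind(scores20, "*" = 0)
  var_all <- pc$sdev^2
  explained <- var_all[seq_len(d)] / sum(var_all)
  structure(list(scores = scores, d = d,
                 explained = explained,
                 cum_explained = cumsum(explained),
                 center = pc$center, scale = pc$scale, rotation = rot),
            class = "property_projection")
}

#' @export
print.property_projection <- function(x, ...) {
  cat(sprintf("<property_projection> d = %d, cumulative variance %.4f\n",
              x$d, x$cum_explained[x$d]))
  invisible(x)
}

#' Persist / restore a property projection as CSV
#'
#' Only the per-letter score vectors are stored (one row per letter including
#' `"*"`); this is all that encoding needs, and keeps the artifact a small
#' plain-text file.
#'
#' @param proj A `property_projection`.
#' @param path CSV path.
#' @return For `read_property_projection`, a `property_projection` carrying
#'   scores only (no refitting metadata).
#' @export
write_property_projection <- function(proj, path) {
  stopifnot(inherits(proj, "property_projection"))
  df <- data.frame(aa = rownames(proj$scores), proj$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_property_projection
#' @export
read_property_projection <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$aa
  if (!identical(rownames(m), AA21))
    stop("projection file rows must be the 21-letter alphabet in order")
  structure(list(scores = m, d = ncol(m),
                 explained = NULL, cum_explained = NULL,
                 center = NULL, scale = NULL, rotation = NULL),
            class = "property_projection")
}

# 21 x (21 + d) lookup: letter -> one-hot block then property block.
.letter_features <- function(proj) {
  d <- proj$d
  feat <- matrix(0, nrow = 21L, ncol = 21L + d,
                 dimnames = list(AA21, NULL))
  feat[cbind(seq_len(21L), seq_len(21L))] <- 1
  feat[, 21L + seq_len(d)] <- proj$scores[AA21, , drop = FALSE]
  feat
}

#' Encode a variant as a per-residue feature matrix
#'
#' Each residue is a length-`21 + d` row: a one-hot block over the 21-letter
#' alphabet (20 amino acids + stop) followed by the property-projection vector
#' of that residue's letter. Rows at unmutated positions equal the wild-type
#' encoding rows.
#'
#' @param v A `dms_variant` (see [parse_variant()]), or a substitution string.
#' @param wt A [wild_type()] object.
#' @param proj A `property_projection` from [fit_property_projection()].
#' @return A numeric matrix of shape `L x (21 + d)`.
#' @export
encode_variant <- function(v, wt, proj) {
  if (is.character(v)) v <- parse_variant(v, wt)
  stopifnot(inherits(v, "dms_variant"), inherits(wt, "wild_type"),
            inherits(proj, "property_projection"))
  feat <- .letter_features(proj)
  letters <- wt$letters
  if (v$n_mut > 0L) letters[v$pos] <- v$mut_aa
  feat[letters, , drop = FALSE]
}

#' Encode many variants into a 3-D batch array
#'
#' Batch counterpart of [encode_variant()], the input format consumed by all
#' models in this package.
#'
#' @param variants Character vector of canonical substitution strings (or a
#'   `dms_dataset`, in which case its variant column is used).
#' @param wt A [wild_type()] object.
#' @param proj A `property_projection`.
#' @return A numeric array of dim `c(n, L, 21 + d)`.
#' @export
encode_variants <- function(variants, wt, proj) {
  if (inherits(variants, "dms_dataset")) variants <- variants$data$variant
  stopifnot(is.character(variants), inherits(wt, "wild_type"),
            inherits(proj, "property_projection"))
  feat <- .letter_features(proj)
  n <- length(variants)
  L <- wt$length
  Fw <- ncol(feat)
  wt_idx <- match(wt$letters, AA21)
  # start from the wild-type row indices, then patch in substitutions
  idx <- matrix(rep(wt_idx, each = n), nrow = n) # n x L letter indices
  nonwt <- which(variants != "")
  if (length(nonwt) > 0L) {
    codes <- strsplit(variants[nonwt], ",", fixed = TRUE)
    row_of <- rep(nonwt, lengths(codes))
    d <- .split_codes(unlist(codes))
    if (any(d$pos < 1L | d$pos > L)) stop("substitution position out of range")
    mi <- match(d$mut_aa, AA21)
    if (anyNA(mi)) stop("unknown mutant letter in variant string")
    idx[cbind(row_of, d$pos)] <- mi
  }
  X <- array(0, dim = c(n, L, Fw))
  for (f in seq_len(Fw)) X[, , f] <- matrix(feat[idx, f], nrow = n)
  X
}

#' Enumerate all single-mutant variants of a wild type
#'
#' One entry per (position, letter) pair over the 20 standard amino acids in
#' alphabet order, position-major. Entries whose letter equals the wild-type
#' letter at that position represent the wild type itself (empty substitution
#' string).
#'
#' @param wt A [wild_type()] object.
#' @param alphabet Letters to substitute (default the 20 standard amino
#'   acids; may include `"*"`).
#' @return A data.frame with columns `pos`, `aa` and `variant`
#'   (`L * length(alphabet)` rows).
#' @export
enumerate_single_mutants <- function(wt, alphabet = aa_alphabet()) {
  stopifnot(inherits(wt, "wild_type"), all(alphabet %in% AA21))
  grid <- expand.grid(aa = alphabet, pos = seq_len(wt$length),
                      stringsAsFactors = FALSE)[, c("pos", "aa")]
  grid <- grid[order(grid$pos), ]
  rownames(grid) <- NULL
  is_wt <- grid$aa == wt$letters[grid$pos]
  grid$variant <- ifelse(is_wt, "",
                         paste0(wt$letters[grid$pos], grid$pos, grid$aa))
  grid
}
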