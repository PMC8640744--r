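# Seeded generator of DMS-like fixtures: an additive + pairwise-epistatic
# fitness landscape with optional global nonlinearity and per-sequence
# Gaussian noise, a variant sampler, and a paired input/selected read-count
# simulator. Every quantity is a pure function of (spec, seed), so fixtures
# are bit-reproducible and never stored on disk.

#' Specify a synthetic fitness landscape
#'
#' The landscape is `g(sum of additive effects + sum of pairwise epistasis)
#' + noise`. Additive effects are per (position, letter), drawn from
#' `N(0, additive_sd)` with wild-type letters fixed at 0. Epistasis is
#' position-level: each of `n_epistatic` randomly chosen position pairs
#' contributes `+/- epistatic_magnitude` whenever *both* positions are
#' mutated (any letters), the simplest mechanism that makes double-mutant
#' effects deviate from the sum of single-mutant effects. Noise is a
#' deterministic function of the sequence and the spec seed, so fitness is a
#' pure function of sequence.
#'
#' Defaults (L = 50, 2000 variants with up to 3 mutations, additive sd 1,
#' 10 epistatic pairs of magnitude 1.5, noise sd 0.1) give a desk-scale
#' landscape in which additive structure dominates — as in real mutational
#' data — with a sparse epistatic signal on top.
#'
#' @param L Sequence length (default 50).
#' @param seed Integer seed fixing the wild type, effects and noise stream.
#' @param additive_sd SD of additive effects (default 1.0).
#' @param n_epistatic Number of epistatic position pairs (default 10).
#' @param epistatic_magnitude Absolute interaction size (default 1.5; signs
#'   are random per pair).
#' @param noise_sd SD of the per-sequence measurement noise (default 0.1).
#' @param nonlinearity `"identity"` (default) or `"tanh"`, a saturating
#'   monotone transform `g(z) = 3 tanh(z/3)` emulating assay saturation.
#' @return An object of class `landscape_spec` containing the wild type, the
#'   additive-effect matrix and the epistatic pair table.
#' @export
landscape_spec <- function(L = 50L, seed = 1L, additive_sd = 1.0,
                           n_epistatic = 10L, epistatic_magnitude = 1.5,
                           noise_sd = 0.1,
                           nonlinearity = c("identity", "tanh")) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(L >= 2L, additive_sd >= 0, noise_sd >= 0, n_epistatic >= 0L)
  if (n_epistatic > choose(L, 2))
    stop("more epistatic pairs than position pairs")
  dat <- withr::with_seed(seed, {
    wt_letters <- sample(AA20, L, replace = TRUE)
    additive <- matrix(stats::rnorm(L * 20L, sd = additive_sd), L, 20L,
                       dimnames = list(NULL, AA20))
    additive[cbind(seq_len(L), match(wt_letters, AA20))] <- 0
    pair_idx <- sample.int(choose(L, 2), n_epistatic)
    all_pairs <- utils::combn(L, 2L)
    pairs <- data.frame(i = all_pairs[1L, pair_idx],
                        j = all_pairs[2L, pair_idx],
                        effect = epistatic_magnitude *
                          sample(c(-1, 1), n_epistatic, replace = TRUE))
    list(wt_letters = wt_letters, additive = additive, pairs = pairs)
  })
  structure(list(L = as.integer(L), seed = as.integer(seed),
                 wild_type = wild_type("synthetic",
                                       paste(dat$wt_letters, collapse = "")),
                 additive = dat$additive, pairs = dat$pairs,
                 additive_sd = additive_sd,
                 epistatic_magnitude = epistatic_magnitude,
                 noise_sd = noise_sd, nonlinearity = nonlinearity),
            class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat(sprintf(paste0("<landscape_spec> L = %d, %d epistatic pairs ",
                     "(|effect| = %.2f), noise sd %.2f, g = %s\n"),
              x$L, nrow(x$pairs), x$epistatic_magnitude, x$noise_sd,
              x$nonlinearity))
  invisible(x)
}

.g_apply <- function(spec, z) {
  switch(spec$nonlinearity,
         identity = z,
         tanh = 3 * tanh(z / 3))
}

# deterministic per-sequence noise: polynomial hash of the variant string
# mixed with the spec seed, used to seed a single normal draw
.seq_noise <- function(spec, variant_strings) {
  if (spec$noise_sd == 0) return(numeric(length(variant_strings)))
  vapply(variant_strings, function(s) {
    h <- 17
    for (code in utf8ToInt(paste0(s, "|", spec$seed)))
      h <- (h * 31 + code) %% 2147483629
    withr::with_seed(as.integer(h), stats::rnorm(1L, sd = spec$noise_sd))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Evaluate landscape fitness for variants
#'
#' @param spec A [landscape_spec()].
#' @param variants Character vector of substitution strings (or a
#'   `dms_dataset` / `dms_variant`).
#' @param noise Include the deterministic per-sequence noise term (default
#'   `TRUE`).
#' @return Numeric vector of fitness values.
#' @export
landscape_fitness <- function(spec, variants, noise = TRUE) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (inherits(variants, "dms_dataset")) variants <- variants$data$variant
  if (inherits(variants, "dms_variant")) variants <- format_variant(variants)
  wt <- spec$wild_type
  vals <- vapply(variants, function(s) {
    v <- parse_variant(s, wt)
    z <- 0
    if (v$n_mut > 0L) {
      z <- sum(spec$additive[cbind(v$pos, match(v$mut_aa, AA20))])
      if (nrow(spec$pairs) > 0L && v$n_mut >= 2L) {
        hit <- spec$pairs$i %in% v$pos & spec$pairs$j %in% v$pos
        z <- z + sum(spec$pairs$effect[hit])
      }
    }
    z
  }, numeric(1), USE.NAMES = FALSE)
  out <- .g_apply(spec, vals)
  if (noise) out <- out + .seq_noise(spec, variants)
  out
}

#' Sample a synthetic DMS dataset from a landscape
#'
#' Draws unique variants with 1 to `max_mutations` substitutions (mutation
#' count uniform, positions uniform without replacement, letters uniform over
#' the 19 non-wild-type letters) and scores them with [landscape_fitness()].
#' The wild type itself is included as the first row when `include_wt` is
#' set, as in real datasets where the wild type anchors the score scale.
#'
#' @param spec A [landscape_spec()].
#' @param n_variants Total variants to return (default 2000, counting the
#'   wild-type row when present).
#' @param max_mutations Maximum substitutions per variant (default 3).
#' @param seed Integer seed (independent of the landscape seed).
#' @param include_wt Include the wild-type row (default `TRUE`).
#' @return A `dms_dataset`; deterministic given `seed`.
#' @export
sample_dataset <- function(spec, n_variants = 2000L, max_mutations = 3L,
                           seed = 1L, include_wt = TRUE) {
  stopifnot(inherits(spec, "landscape_spec"), n_variants >= 1L,
            max_mutations >= 1L, max_mutations <= spec$L)
  wt <- spec$wild_type
  space <- sum(vapply(seq_len(max_mutations), function(k)
    choose(spec$L, k) * 19^k, numeric(1))) + as.numeric(include_wt)
  if (n_variants > space)
    stop("requested ", n_variants, " variants but only ", space,
         " exist with <= ", max_mutations, " mutations")
  n_mutants <- n_variants - as.integer(include_wt)
  variants <- withr::with_seed(seed, {
    seen <- character(0)
    while (length(seen) < n_mutants) {
      need <- n_mutants - length(seen)
      fresh <- vapply(seq_len(max(need, 16L)), function(dummy) {
        k <- sample.int(max_mutations, 1L)
        pos <- sort(sample.int(spec$L, k))
        mut <- vapply(pos, function(p)
          sample(setdiff(AA20, wt$letters[p]), 1L), character(1))
        paste0(wt$letters[pos], pos, mut, collapse = ",")
      }, character(1))
      seen <- unique(c(seen, fresh))
    }
    seen[seq_len(n_mutants)]
  })
  if (include_wt) variants <- c("", variants)
  dms_dataset(wt, variants, landscape_fitness(spec, variants))
}

#' Simulate paired input / selected read counts for a dataset
#'
#' Input-pool counts are multinomial over a seeded log-normal abundance
#' distribution (libraries are never uniform in practice); selected-pool
#' counts are multinomial with probabilities proportional to
#' `input frequency * plogis(selection_strength * score)`, emulating a
#' single-round functional selection. The read budget is split evenly
#' between the two pools, so the grand total equals `total_reads` exactly.
#'
#' @param ds A `dms_dataset` (should include the wild-type row if downstream
#'   scoring normalizes to it).
#' @param total_reads Total reads across both pools.
#' @param selection_strength Logistic selection coefficient (0 = neutral;
#'   default 1).
#' @param seed Integer seed.
#' @param wt_frequency Input-library frequency reserved for the wild-type row
#'   (`""`), if present (default 0.05). Wild-type-normalized scoring needs a
#'   reliably covered reference, so scans are run with the reference well
#'   represented; a spiked-in frequency reproduces that.
#' @return A `read_count_table` aligned to the dataset's variants.
#' @export
simulate_read_counts <- function(ds, total_reads, selection_strength = 1,
                                 seed = 1L, wt_frequency = 0.05) {
  stopifnot(inherits(ds, "dms_dataset"), total_reads >= 2L,
            wt_frequency >= 0, wt_frequency < 1)
  n <- n_variants(ds)
  n_input <- floor(total_reads / 2)
  n_selected <- total_reads - n_input
  wt_row <- which(ds$data$variant == "")
  counts <- withr::with_seed(seed, {
    abundance <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    if (length(wt_row) == 1L && wt_frequency > 0) {
      abundance[wt_row] <- 0
      abundance[wt_row] <- wt_frequency / (1 - wt_frequency) * sum(abundance)
    }
    p_in <- abundance / sum(abundance)
    surv <- stats::plogis(selection_strength * ds$data$score)
    p_sel <- p_in * surv
    p_sel <- p_sel / sum(p_sel)
    list(inp = as.numeric(stats::rmultinom(1L, n_input, p_in)),
         sel = as.numeric(stats::rmultinom(1L, n_selected, p_sel)))
  })
  count_table(ds$data$variant, counts$inp, counts$sel)
}
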