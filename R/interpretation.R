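# Model interpretation: integrated-gradients attributions against the
# wild-type baseline, per-position aggregation, latent-representation
# extraction, and the complete single-mutant prediction matrix.

#' Integrated-gradients attributions for one encoded variant
#'
#' Distributes `f(x) - f(baseline)` over input features by integrating the
#' model gradient along the straight path from the baseline encoding to the
#' variant encoding:
#' `attr_f = (x_f - x'_f) * (1/steps) * sum_k grad_f f(x' + alpha_k (x - x'))`.
#' The Riemann sum uses the midpoint rule (`alpha_k = (k - 0.5)/steps`),
#' which converges faster than the left/right rules at the same step count.
#' The wild-type encoding is the conventional baseline, so attributions read
#' as the contribution of each mutation-induced feature change.
#'
#' @param m A `dms_model`.
#' @param x Encoded variant, `L x (21+d)` matrix.
#' @param baseline Baseline encoding of the same shape (typically
#'   `encode_variant("", wt, proj)`).
#' @param steps Number of path points (default 100).
#' @return `L x (21+d)` matrix of attributions; they sum approximately to
#'   `f(x) - f(baseline)` (exactly, for a linear model).
#' @export
integrated_gradients <- function(m, x, baseline, steps = 100L) {
  stopifnot(inherits(m, "dms_model"), is.matrix(x), is.matrix(baseline),
            identical(dim(x), dim(baseline)), steps >= 1L)
  .as_batch(x, m)
  delta <- x - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  path <- array(0, dim = c(steps, nrow(x), ncol(x)))
  for (k in seq_len(steps)) path[k, , ] <- baseline + alphas[k] * delta
  fw <- nn_forward(m$layers, path)
  bw <- nn_backward(m$layers, fw$caches, rep(1, steps))
  mean_grad <- apply(bw$dX, c(2L, 3L), mean)
  delta * mean_grad
}

#' Aggregate attributions per sequence position
#'
#' @param a An `L x (21+d)` attribution matrix from [integrated_gradients()].
#' @return Length-`L` numeric vector of per-position attribution sums.
#' @export
position_attributions <- function(a) {
  stopifnot(is.matrix(a))
  rowSums(a)
}

#' Dataset-level per-position attributions
#'
#' Computes integrated gradients for every variant in a dataset (against the
#' wild-type baseline) and sums the per-position attributions across
#' variants, yielding one importance value per sequence position. Negative
#' values mark positions where mutations push the model toward lower scores.
#'
#' @param m A `dms_model`.
#' @param ds A `dms_dataset` (typically the training set).
#' @param wt A [wild_type()] object.
#' @param proj A `property_projection`.
#' @param steps Path points per variant (default 100).
#' @return Length-`L` numeric vector (zero for an empty dataset).
#' @export
dataset_position_attributions <- function(m, ds, wt, proj, steps = 100L) {
  stopifnot(inherits(ds, "dms_dataset"))
  baseline <- encode_variant("", wt, proj)
  total <- numeric(wt$length)
  for (v in ds$data$variant) {
    x <- encode_variant(v, wt, proj)
    total <- total + position_attributions(
      integrated_gradients(m, x, baseline, steps))
  }
  total
}

#' Latent representations at the last internal layer
#'
#' Returns each variant's activation vector at the layer feeding the output
#' node (dropout disabled), i.e. the network's learned representation of the
#' sequence. For the convolutional architectures with the default head this
#' is a length-100 vector per variant.
#'
#' @param m A `dms_model` with at least one hidden layer (the linear model
#'   has no internal representation and is rejected).
#' @param X Encoded batch array `(n, L, 21+d)`.
#' @return `n x width` numeric matrix.
#' @export
latent_representations <- function(m, X) {
  stopifnot(inherits(m, "dms_model"))
  if (length(m$layers) <= 2L)
    stop("model has no internal layer (linear regression has no latent space)")
  X <- .as_batch(X, m)
  fw <- nn_forward(m$layers, X, keep_outputs = TRUE)
  latent <- fw$outputs[[length(m$layers) - 1L]]
  if (!is.matrix(latent)) latent <- matrix(latent, nrow = dim(X)[1])
  latent
}

#' Predictions for every possible single mutation
#'
#' Builds the complete `L x 21` prediction matrix over all (position, letter)
#' cells, including the stop codon and mutations never observed in training
#' data. Cells whose letter equals the wild-type letter carry the wild-type
#' prediction and are flagged in `wt_mask`.
#'
#' @param m A `dms_model`.
#' @param wt A [wild_type()] object.
#' @param proj A `property_projection`.
#' @param alphabet Letters to scan (default the 21-letter alphabet including
#'   `"*"`).
#' @return An object of class `single_mutant_matrix`: list with `pred`
#'   (`L x length(alphabet)` matrix, rownames positions, colnames letters) and
#'   logical `wt_mask` of the same shape.
#' @export
single_mutant_matrix <- function(m, wt, proj,
                                 alphabet = aa_alphabet_stop()) {
  grid <- enumerate_single_mutants(wt, alphabet)
  X <- encode_variants(grid$variant, wt, proj)
  pred <- predict(m, X)
  P <- matrix(pred, nrow = wt$length, ncol = length(alphabet), byrow = TRUE,
              dimnames = list(seq_len(wt$length), alphabet))
  mask <- matrix(grid$aa == wt$letters[grid$pos],
                 nrow = wt$length, ncol = length(alphabet), byrow = TRUE,
                 dimnames = dimnames(P))
  structure(list(pred = P, wt_mask = mask), class = "single_mutant_matrix")
}

#' @export
print.single_mutant_matrix <- function(x, ...) {
  cat(sprintf("<single_mutant_matrix> %d positions x %d letters\n",
              nrow(x$pred), ncol(x$pred)))
  invisible(x)
}

#' Write a single-mutant matrix as CSV
#'
#' One row per position, one column per letter; wild-type cells are written
#' as-is (they equal the wild-type prediction).
#'
#' @param smm A `single_mutant_matrix`.
#' @param path CSV path.
#' @export
write_single_mutant_matrix <- function(smm, path) {
  stopifnot(inherits(smm, "single_mutant_matrix"))
  utils::write.csv(as.data.frame(smm$pred), path, row.names = TRUE)
  invisible(path)
}
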