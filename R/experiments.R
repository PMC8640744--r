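# Dataset splitting (random, reduced-size, mutational / positional
# extrapolation), model training with early stopping, and the ranking metrics
# used to evaluate sequence-function models.

.new_split <- function(strategy, train, tune, test, discarded, seed) {
  structure(list(strategy = strategy,
                 train = as.integer(train), tune = as.integer(tune),
                 test = as.integer(test), discarded = as.integer(discarded),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %s: %d train / %d tune / %d test (%d discarded)\n",
              x$strategy, length(x$train), length(x$tune), length(x$test),
              length(x$discarded)))
  invisible(x)
}

#' Random train / tune / test split
#'
#' Default fractions are 81% training, 9% tuning and 10% testing. The tuning
#' and testing sizes are floors of their fractions and the remainder goes to
#' training, so training is never starved on small datasets.
#'
#' @param ds A `dms_dataset`.
#' @param fractions Numeric length-3 vector (train, tune, test) summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A `split_spec` whose index sets are pairwise disjoint and cover the
#'   dataset.
#' @export
split_random <- function(ds, fractions = c(0.81, 0.09, 0.10), seed = 1L) {
  stopifnot(inherits(ds, "dms_dataset"), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- n_variants(ds)
  if (n < 3L) stop("dataset must have at least 3 variants to split")
  n_tune <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  perm <- withr::with_seed(seed, sample.int(n))
  tune <- perm[seq_len(n_tune)]
  test <- perm[n_tune + seq_len(n_test)]
  train <- if (n_tune + n_test > 0L) perm[-seq_len(n_tune + n_test)] else perm
  .new_split("random", train, tune, test, integer(0), seed)
}

# substitution codes per variant, as a list of character vectors
.variant_codes <- function(ds) {
  v <- ds$data$variant
  out <- strsplit(v, ",", fixed = TRUE)
  out[v == ""] <- list(character(0))
  out
}

.extrapolation_split <- function(ds, keys_per_variant, fraction, seed,
                                 what) {
  all_keys <- sort(unique(unlist(keys_per_variant)))
  if (length(all_keys) < 2L)
    stop("dataset must contain at least 2 distinct ", what)
  n_train_keys <- round(fraction * length(all_keys))
  if (n_train_keys < 1L || n_train_keys >= length(all_keys))
    stop("fraction leaves an empty train or test ", what, " pool")
  train_keys <- withr::with_seed(
    seed, sample(all_keys, n_train_keys))
  in_train <- vapply(keys_per_variant,
                     function(k) all(k %in% train_keys), logical(1))
  in_test <- vapply(keys_per_variant, function(k)
    length(k) > 0L && !any(k %in% train_keys), logical(1))
  pool <- which(in_train) # wild-type rows (no keys) fall here
  test <- which(in_test)
  discarded <- setdiff(seq_along(keys_per_variant), c(pool, test))
  if (length(test) == 0L)
    stop("empty test pool; try a different seed")
  if (length(pool) < 2L)
    stop("training pool too small; try a different seed")
  n_tune <- floor(0.1 * length(pool))
  perm <- withr::with_seed(seed + 1L, sample(pool))
  tune <- perm[seq_len(n_tune)]
  train <- perm[-seq_len(n_tune)]
  if (n_tune == 0L) train <- perm
  list(train = train, tune = tune, test = test, discarded = discarded)
}

#' Mutational-extrapolation split
#'
#' Designates 80% (by default) of the distinct single mutations present in the
#' dataset as training mutations and the rest as testing mutations. Variants
#' carrying only training mutations form the training pool (split 90/10 into
#' train and tune); variants carrying only testing mutations form the test
#' set; variants mixing the two are discarded, so no mutation seen at train
#' time ever occurs in the test set.
#'
#' @param ds A `dms_dataset`.
#' @param mutation_fraction Fraction of distinct mutations designated as
#'   training (default 0.8).
#' @param seed Integer seed.
#' @return A `split_spec` with a non-empty `discarded` slot in general.
#' @export
split_mutational <- function(ds, mutation_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "dms_dataset"))
  codes <- .variant_codes(ds)
  parts <- .extrapolation_split(ds, codes, mutation_fraction, seed,
                                "single mutations")
  .new_split("mutational", parts$train, parts$tune, parts$test,
             parts$discarded, seed)
}

#' Positional-extrapolation split
#'
#' Like [split_mutational()], but designates sequence *positions*: test-set
#' variants carry mutations only at positions never mutated in the training
#' data.
#'
#' @param ds A `dms_dataset`.
#' @param position_fraction Fraction of mutated positions designated as
#'   training (default 0.8).
#' @param seed Integer seed.
#' @return A `split_spec`.
#' @export
split_positional <- function(ds, position_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "dms_dataset"))
  codes <- .variant_codes(ds)
  pos <- lapply(codes, function(k)
    if (length(k) == 0L) integer(0)
    else as.integer(substr(k, 2L, nchar(k) - 1L)))
  parts <- .extrapolation_split(ds, pos, position_fraction, seed,
                                "mutated positions")
  .new_split("positional", parts$train, parts$tune, parts$test,
             parts$discarded, seed)
}

#' Sample reduced-size training sets
#'
#' Draws `replicates` random subsets of each requested size from the training
#' pool (only), for learning-curve experiments; downstream summaries should
#' take the median metric over the replicates.
#'
#' @param pool Integer vector of training-pool indices (e.g.
#'   `split$train`).
#' @param sizes Integer vector of subset sizes (each `<= length(pool)`).
#' @param replicates Subsets per size (default 5).
#' @param seed Integer seed.
#' @return A named list (one element per size) of lists of index vectors.
#' @export
reduced_training_sets <- function(pool, sizes, replicates = 5L, seed = 1L) {
  stopifnot(all(sizes >= 1L), all(sizes <= length(pool)))
  withr::with_seed(seed, {
    out <- lapply(sizes, function(sz)
      lapply(seq_len(replicates), function(r) sort(sample(pool, sz))))
  })
  names(out) <- as.character(sizes)
  out
}

#' Training configuration
#'
#' Adam with default moment parameters, mean-squared-error loss, and epoch-
#' level early stopping: training stops once the tuning loss has failed to
#' improve by at least `min_delta` for `patience` consecutive epochs, and the
#' parameters from the best tuning-loss epoch are restored. The tuning loss is
#' the exact unweighted mean squared error over all tuning examples.
#'
#' @param lr Learning rate (default 0.001, the Adam default).
#' @param batch_size Minibatch size (default 128).
#' @param max_epochs Hard epoch cap (default 300).
#' @param patience Early-stopping patience in epochs (default 15).
#' @param min_delta Minimum tuning-loss improvement (default 1e-5).
#' @param seed Integer seed for shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr = 0.001, batch_size = 128L, max_epochs = 300L,
                            patience = 15L, min_delta = 1e-5, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1L, patience < max_epochs)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train a model on encoded data
#'
#' @param m An untrained (or previously trained) `dms_model`.
#' @param X_train,y_train Encoded training batch (array `(n, L, F)`) and
#'   scores.
#' @param X_tune,y_tune Tuning batch used for early stopping.
#' @param config A [training_config()].
#' @return The trained `dms_model`; `$history` holds a data.frame of per-epoch
#'   train and tune losses and `$best_epoch` the restored epoch.
#' @export
train_model <- function(m, X_train, y_train, X_tune, y_tune,
                        config = training_config()) {
  stopifnot(inherits(m, "dms_model"), inherits(config, "training_config"))
  X_train <- .as_batch(X_train, m)
  X_tune <- .as_batch(X_tune, m)
  fit <- nn_fit(m$layers, X_train, as.numeric(y_train),
                X_tune, as.numeric(y_tune),
                lr = config$lr, batch_size = config$batch_size,
                max_epochs = config$max_epochs, patience = config$patience,
                min_delta = config$min_delta, seed = config$seed)
  m$layers <- fit$layers
  m$trained <- TRUE
  m$history <- fit$history
  m$best_epoch <- fit$best_epoch
  m$best_tune_loss <- fit$best_tune_loss
  m
}

#' Correlation and error metrics on a test set
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return An object of class `eval_report`: list with `pearson`, `spearman`,
#'   `mse` and `n`. If either vector has zero variance the correlations are
#'   `NaN` and a warning is raised.
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2L)
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("zero-variance predictions or truth; correlations are NaN")
    pe <- NaN
    sp <- NaN
  } else {
    pe <- stats::cor(pred, truth)
    sp <- stats::cor(pred, truth, method = "spearman")
  }
  structure(list(pearson = pe, spearman = sp,
                 mse = mean((pred - truth)^2), n = length(pred)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, Pearson %.4f, Spearman %.4f, MSE %.5f\n",
              x$n, x$pearson, x$spearman, x$mse))
  invisible(x)
}

#' Evaluate a model on an encoded test set
#'
#' @param m A `dms_model`.
#' @param X_test Encoded batch.
#' @param y_test True scores.
#' @param budgets Optional integer vector; when given (and the test set has
#'   at least `top_k` variants), the report gains a `curves` data.frame with
#'   the recall-at-budget and top-N mean/max score curves at those budgets.
#' @param top_k True top-set size for the recall curve (default 100).
#' @return An `eval_report` (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(m, X_test, y_test, budgets = NULL, top_k = 100L) {
  pred <- predict(m, X_test)
  y_test <- as.numeric(y_test)
  rep <- evaluate_predictions(pred, y_test)
  if (!is.null(budgets)) {
    rep$curves <- data.frame(
      budget = budgets,
      recall = vapply(budgets, function(b)
        recall_at_budget(pred, y_test, b, top_k), numeric(1)),
      top_mean = vapply(budgets, function(b)
        top_n_stats(pred, y_test, b)$mean, numeric(1)),
      top_max = vapply(budgets, function(b)
        top_n_stats(pred, y_test, b)$max, numeric(1)))
  }
  rep
}

# indices of the top-n entries of x, descending, ties broken by index
.top_idx <- function(x, n) order(-x, seq_along(x))[seq_len(n)]

#' Recall of the true top variants at a testing budget
#'
#' The fraction of the true `top_k` best-scoring variants that appear among
#' the model's `budget` top-ranked predictions. Ranking ties are broken by
#' variant index (stable), so the metric is deterministic.
#'
#' @param pred Predicted scores.
#' @param truth True scores (same length, at least `top_k`).
#' @param budget Number of variants the model may nominate.
#' @param top_k Size of the true top set (default 100).
#' @return A fraction in `[0, 1]`.
#' @export
recall_at_budget <- function(pred, truth, budget, top_k = 100L) {
  stopifnot(length(pred) == length(truth), budget >= 1L,
            length(truth) >= top_k, budget <= length(pred))
  true_top <- .top_idx(truth, top_k)
  pred_top <- .top_idx(pred, budget)
  length(intersect(pred_top, true_top)) / top_k
}

#' Mean and maximum true score of the top-N predictions
#'
#' @param pred,truth Numeric vectors of equal length.
#' @param n Budget.
#' @return Named list with `mean` and `max` of the true scores of the `n`
#'   top-predicted variants.
#' @export
top_n_stats <- function(pred, truth, n) {
  stopifnot(length(pred) == length(truth), n >= 1L, n <= length(pred))
  sel <- truth[.top_idx(pred, n)]
  list(mean = mean(sel), max = max(sel))
}

#' Random-ranking baseline for recall curves
#'
#' Generates `R` random rankings of a test set of the given size and reports,
#' for every budget, the mean recall of the true top `top_k` variants and a
#' 95% confidence band computed as 1.96 times the standard deviation across
#' rankings.
#'
#' @param test_size Test-set size.
#' @param budgets Integer vector of budgets.
#' @param top_k True top-set size (default 100).
#' @param R Number of random rankings (default 1000).
#' @param seed Integer seed.
#' @return A data.frame with columns `budget`, `mean_recall`,
#'   `ci_halfwidth`.
#' @export
random_baseline <- function(test_size, budgets, top_k = 100L, R = 1000L,
                            seed = 1L) {
  stopifnot(test_size >= top_k, all(budgets >= 1L),
            all(budgets <= test_size))
  # recall of a uniformly random ranking depends only on how many of the
  # first `budget` ranks land in the true top set; simulate the rank
  # positions of the top_k true variants directly
  rec <- withr::with_seed(seed, {
    vapply(seq_len(R), function(r) {
      ranks <- sample.int(test_size, top_k)
      vapply(budgets, function(b) sum(ranks <= b) / top_k, numeric(1))
    }, numeric(length(budgets)))
  })
  rec <- matrix(rec, nrow = length(budgets))
  data.frame(budget = budgets,
             mean_recall = rowMeans(rec),
             ci_halfwidth = 1.96 * apply(rec, 1L, stats::sd))
}
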