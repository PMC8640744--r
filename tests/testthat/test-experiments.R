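test_that("random split has floor-based 81/9/10 sizes and is deterministic", {
  spec <- landscape_spec(L = 10L, seed = 2L)
  ds <- sample_dataset(spec, n_variants = 1000L, seed = 3L)
  sp <- split_random(ds, seed = 11L)
  expect_equal(length(sp$train), 810L)
  expect_equal(length(sp$tune), 90L)
  expect_equal(length(sp$test), 100L)
  expect_equal(sort(c(sp$train, sp$tune, sp$test)), 1:1000)
  sp2 <- split_random(ds, seed = 11L)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_random(ds, seed = 12L)))
  # floors go to tune/test, remainder to train
  small <- subset_dataset(ds, 1:17)
  s3 <- split_random(small, seed = 1L)
  expect_equal(lengths(s3[c("train", "tune", "test")]),
               c(train = 15L, tune = 1L, test = 1L))
  expect_error(split_random(subset_dataset(ds, 1:2)), "at least 3")
})

test_that("extrapolation splits have empty information overlap", {
  codes_of <- function(ds, idx) {
    v <- ds$data$variant[idx]
    unique(unlist(strsplit(v[v != ""], ",", fixed = TRUE)))
  }
  pos_of <- function(ds, idx) {
    k <- codes_of(ds, idx)
    unique(as.integer(substr(k, 2L, nchar(k) - 1L)))
  }
  for (s in 1:5) {
    spec <- landscape_spec(L = 15L, seed = s)
    ds <- sample_dataset(spec, n_variants = 120L, seed = s + 50L)
    sm <- split_mutational(ds, seed = s)
    expect_length(intersect(codes_of(ds, c(sm$train, sm$tune)),
                            codes_of(ds, sm$test)), 0L)
    sp <- split_positional(ds, seed = s)
    expect_length(intersect(pos_of(ds, c(sp$train, sp$tune)),
                            pos_of(ds, sp$test)), 0L)
    for (x in list(sm, sp)) {
      idx <- c(x$train, x$tune, x$test, x$discarded)
      expect_equal(sort(idx), seq_len(n_variants(ds))) # partition
      expect_equal(anyDuplicated(idx), 0L)
      # train:tune is 9:1 within the pool
      pool <- length(x$train) + length(x$tune)
      expect_equal(length(x$tune), floor(0.1 * pool))
    }
  }
})

test_that("mutational split pools follow the toy example", {
  # variants made of mutations {A: M1C, B: T2A} and {C: E3Q}: any variant
  # mixing a train- and a test-designated mutation must be discarded, and
  # every other variant lands with its own designations
  wt <- toy_wt()
  ds <- dms_dataset(wt, c("M1C", "T2A", "M1C,T2A", "E3Q", "M1C,E3Q"),
                    1:5 / 10)
  found <- FALSE
  for (s in 1:20) {
    sp <- try(split_mutational(ds, mutation_fraction = 2 / 3, seed = s),
              silent = TRUE)
    if (inherits(sp, "try-error")) next
    test_codes <- unique(unlist(strsplit(ds$data$variant[sp$test], ",")))
    if (setequal(test_codes, "E3Q")) {
      found <- TRUE
      expect_setequal(c(sp$train, sp$tune), 1:3)
      expect_equal(sp$test, 4L)
      expect_equal(sp$discarded, 5L)
    }
  }
  expect_true(found)
})

test_that("reduced training sets stay inside the pool", {
  pool <- 11:90
  sets <- reduced_training_sets(pool, sizes = c(10L, 80L), replicates = 5L,
                                seed = 4L)
  expect_named(sets, c("10", "80"))
  expect_length(sets[["10"]], 5L)
  for (r in sets[["10"]]) {
    expect_length(r, 10L)
    expect_true(all(r %in% pool))
  }
  # size = pool size: every replicate is the whole pool
  for (r in sets[["80"]]) expect_equal(r, pool)
  expect_identical(reduced_training_sets(pool, 10L, seed = 4L),
                   reduced_training_sets(pool, 10L, seed = 4L))
})

test_that("training recovers a noiseless additive landscape and stops early", {
  prob <- tiny_problem(L = 12L, n = 250L, seed = 21L)
  sp <- split_random(prob$ds, seed = 1L)
  m <- build_model(model_spec("linear", seed = 1L), prob$wt$length,
                   dim(prob$X)[3])
  cfg <- training_config(lr = 0.01, batch_size = 32L, seed = 1L)
  m <- train_model(m, prob$X[sp$train, , ], prob$y[sp$train],
                   prob$X[sp$tune, , ], prob$y[sp$tune], cfg)
  ev <- evaluate_model(m, prob$X[sp$train, , ], prob$y[sp$train])
  expect_gte(ev$pearson, 0.99) # least-squares recovery
  h <- m$history
  expect_lte(nrow(h), 300L)
  # early stopping: restored parameters achieve the minimum tuning loss seen
  expect_equal(m$best_tune_loss, min(h$tune_loss), tolerance = 1e-12)
  expect_lte(m$best_tune_loss, h$tune_loss[nrow(h)])
  if (nrow(h) < cfg$max_epochs) # stopped by patience, 15 epochs after best
    expect_equal(nrow(h) - m$best_epoch, cfg$patience)
})

test_that("nonlinear models beat linear when planted epistasis is learnable", {
  # property over seeds: on a landscape whose pairwise interactions are each
  # observed tens of times (L = 15, 1500 variants, 8 pairs), a fully
  # connected net must achieve lower test MSE than linear regression
  proj <- test_proj()
  diffs <- vapply(1:3, function(s) {
    spec <- landscape_spec(L = 15L, seed = s, n_epistatic = 8L,
                           epistatic_magnitude = 2, noise_sd = 0.05)
    ds <- sample_dataset(spec, n_variants = 1500L, seed = s + 100L)
    sp <- split_random(ds, seed = s)
    Xd <- encode_variants(ds, spec$wild_type, proj)
    mse_of <- function(mspec, lr) {
      m <- build_model(mspec, spec$L, dim(Xd)[3])
      m <- train_model(m, Xd[sp$train, , ], ds$data$score[sp$train],
                       Xd[sp$tune, , ], ds$data$score[sp$tune],
                       training_config(lr = lr, batch_size = 128L, seed = s))
      evaluate_model(m, Xd[sp$test, , ], ds$data$score[sp$test])$mse
    }
    mse_of(model_spec("linear", seed = s), 0.03) -
      mse_of(model_spec("fully_connected", hidden = 100L, seed = s), 0.01)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_true(all(diffs > 0))
})

test_that("training_config validates and train_model rejects bad shapes", {
  expect_error(training_config(patience = 300L, max_epochs = 300L),
               "patience")
  expect_error(training_config(lr = 0), "lr")
  prob <- tiny_problem(L = 12L, n = 60L)
  m <- build_model(model_spec("linear"), 99L, dim(prob$X)[3])
  expect_error(train_model(m, prob$X, prob$y, prob$X, prob$y),
               "does not match model")
})

test_that("evaluation metrics behave at the extremes", {
  truth <- c(3, 1, 4, 1, 5, 9, 2, 6)
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(perfect$pearson, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(evaluate_predictions(-truth, truth)$pearson, -1)
  expect_warning(rep0 <- evaluate_predictions(rep(1, 8), truth),
                 "zero-variance")
  expect_true(is.nan(rep0$pearson))
})

test_that("recall_at_budget matches a brute-force set intersection", {
  withr::with_seed(31L, {
    truth <- rnorm(40)
    pred <- rnorm(40)
  })
  for (budget in c(1L, 5L, 17L, 40L)) {
    k <- 10L
    brute <- length(intersect(order(pred, decreasing = TRUE)[1:budget],
                              order(truth, decreasing = TRUE)[1:k])) / k
    expect_equal(recall_at_budget(pred, truth, budget, top_k = k), brute)
  }
  expect_equal(recall_at_budget(pred, truth, 40L, top_k = 10L), 1)
  expect_equal(recall_at_budget(truth, truth, 10L, top_k = 10L), 1)
})

test_that("top_n_stats matches brute force and its trivial cases", {
  withr::with_seed(32L, {
    truth <- rnorm(30)
    pred <- rnorm(30)
  })
  n <- 7L
  sel <- truth[order(pred, decreasing = TRUE)[1:n]]
  st <- top_n_stats(pred, truth, n)
  expect_equal(st$mean, mean(sel))
  expect_equal(st$max, max(sel))
  expect_equal(top_n_stats(truth, truth, 5L)$max, max(truth))
  expect_equal(top_n_stats(pred, truth, 30L)$mean, mean(truth))
})

test_that("random baseline matches the hypergeometric expectation", {
  rb <- random_baseline(200L, budgets = c(20L, 100L, 200L), top_k = 50L,
                        R = 1000L, seed = 8L)
  # E[recall at N] = N / test_size for a uniformly random ranking
  expect_lte(abs(rb$mean_recall[1] - 20 / 200), rb$ci_halfwidth[1])
  expect_lte(abs(rb$mean_recall[2] - 100 / 200), rb$ci_halfwidth[2])
  expect_equal(rb$mean_recall[3], 1)
  expect_equal(rb$ci_halfwidth[3], 0)
})
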