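test_that("integrated gradients vanish on the baseline itself", {
  prob <- tiny_problem(L = 8L, n = 60L)
  m <- build_model(model_spec("fully_connected", hidden = 12L, seed = 3L),
                   prob$wt$length, dim(prob$X)[3])
  base <- encode_variant("", prob$wt, prob$proj)
  a <- integrated_gradients(m, base, base, steps = 10L)
  expect_equal(a, base * 0)
})

test_that("integrated gradients are exact for the linear model", {
  prob <- tiny_problem(L = 8L, n = 60L)
  m <- build_model(model_spec("linear", seed = 5L), prob$wt$length,
                   dim(prob$X)[3])
  L <- prob$wt$length; Fw <- dim(prob$X)[3]
  W <- matrix(m$layers[[2]]$W[, 1], L, Fw) # flatten is position-fastest
  base <- encode_variant("", prob$wt, prob$proj)
  v <- paste0(prob$wt$letters[2], 2,
              setdiff(aa_alphabet(), prob$wt$letters[2])[1])
  x <- encode_variant(v, prob$wt, prob$proj)
  for (steps in c(1L, 7L, 100L)) {
    a <- integrated_gradients(m, x, base, steps = steps)
    expect_equal(a, W * (x - base), tolerance = 1e-10, ignore_attr = TRUE)
  }
  # completeness is exact in the linear case
  a <- integrated_gradients(m, x, base, steps = 3L)
  expect_equal(sum(a), predict(m, x) - predict(m, base), tolerance = 1e-10)
})

test_that("completeness error shrinks as steps grow on a nonlinear net", {
  prob <- tiny_problem(L = 8L, n = 60L)
  m <- build_model(model_spec("fully_connected", hidden = c(16L, 8L),
                              seed = 11L),
                   prob$wt$length, dim(prob$X)[3])
  base <- encode_variant("", prob$wt, prob$proj)
  v <- prob$ds$data$variant[which(mutation_counts(prob$ds) == 2L)[1]]
  x <- encode_variant(v, prob$wt, prob$proj)
  delta_f <- predict(m, x) - predict(m, base)
  errs <- vapply(c(10L, 100L, 1000L), function(st)
    abs(sum(integrated_gradients(m, x, base, steps = st)) - delta_f),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-12)) # monotone decrease
  expect_lt(errs[2], 1e-3)
})

test_that("position attributions aggregate consistently", {
  prob <- tiny_problem(L = 8L, n = 40L)
  m <- build_model(model_spec("fully_connected", hidden = 10L, seed = 2L),
                   prob$wt$length, dim(prob$X)[3])
  base <- encode_variant("", prob$wt, prob$proj)
  v <- prob$ds$data$variant[5]
  a <- integrated_gradients(m, encode_variant(v, prob$wt, prob$proj), base,
                            steps = 20L)
  pv <- position_attributions(a)
  expect_length(pv, prob$wt$length)
  expect_equal(sum(pv), sum(a))
  # dataset-level vector is the sum of per-variant vectors
  two <- subset_dataset(prob$ds, c(5L, 9L))
  d2 <- dataset_position_attributions(m, two, prob$wt, prob$proj,
                                      steps = 20L)
  v9 <- position_attributions(
    integrated_gradients(m, encode_variant(prob$ds$data$variant[9],
                                           prob$wt, prob$proj),
                         base, steps = 20L))
  expect_equal(d2, pv + v9, tolerance = 1e-10)
  empty <- subset_dataset(prob$ds, integer(0))
  expect_equal(dataset_position_attributions(m, empty, prob$wt, prob$proj),
               numeric(prob$wt$length))
})

test_that("latent representations come from the layer feeding the output", {
  prob <- tiny_problem(L = 12L, n = 40L)
  m <- build_model(model_spec("seq_conv", filters = 4L, kernel = 3L,
                              seed = 6L),
                   prob$wt$length, dim(prob$X)[3])
  Z <- latent_representations(m, prob$X[1:6, , ])
  expect_equal(dim(Z), c(6L, 100L)) # default dense head width
  # identical variants give identical rows
  Xdup <- prob$X[c(1L, 1L), , ]
  Zdup <- latent_representations(m, Xdup)
  expect_equal(Zdup[1, ], Zdup[2, ])
  lin <- build_model(model_spec("linear"), prob$wt$length, dim(prob$X)[3])
  expect_error(latent_representations(lin, prob$X), "no latent space")
})

test_that("single-mutant matrix is complete, including the stop codon", {
  prob <- tiny_problem(L = 8L, n = 40L)
  m <- build_model(model_spec("linear", seed = 8L), prob$wt$length,
                   dim(prob$X)[3])
  smm <- single_mutant_matrix(m, prob$wt, prob$proj)
  expect_equal(dim(smm$pred), c(8L, 21L))
  expect_equal(colnames(smm$pred), aa_alphabet_stop())
  expect_false(any(is.na(smm$pred))) # no gaps, even unobserved mutations
  expect_equal(sum(smm$wt_mask), 8L) # one wild-type cell per position
  wt_pred <- predict(m, encode_variant("", prob$wt, prob$proj))
  expect_equal(unname(smm$pred[smm$wt_mask]), rep(wt_pred, 8L),
               tolerance = 1e-12)
  # spot-check one cell against a direct prediction
  v <- paste0(prob$wt$letters[4], 4,
              setdiff(aa_alphabet(), prob$wt$letters[4])[2])
  aa <- substr(v, nchar(v), nchar(v))
  expect_equal(smm$pred[4, aa],
               predict(m, encode_variant(v, prob$wt, prob$proj)),
               ignore_attr = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_single_mutant_matrix(smm, path)
  back <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back), smm$pred, tolerance = 1e-6,
               ignore_attr = TRUE)
})
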