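test_that("graph convolution reproduces the hand-worked two-node example", {
  g <- igraph::make_graph(c(1, 2), n = 2, directed = FALSE)
  X <- rbind(c(1, 0), c(0, 1))
  params <- list(W_C = matrix(c(1, 2), 2, 1), W_N = matrix(c(3, 4), 2, 1),
                 b = 0)
  Z <- graph_conv_apply(X, g, params)
  expect_equal(as.numeric(Z), c(5, 5))
  expect_equal(naive_graph_conv(X, g, params), Z)
})

test_that("graph convolution matches the per-node loop oracle", {
  for (case in 1:25) {
    withr::with_seed(case, {
      L <- sample(2:8, 1)
      f_in <- sample(1:5, 1)
      f_out <- sample(1:4, 1)
      g <- random_graph(L, p = runif(1, 0.2, 0.8), seed = case + 100L)
      X <- matrix(rnorm(L * f_in), L, f_in)
      params <- list(W_C = matrix(rnorm(f_in * f_out), f_in, f_out),
                     W_N = matrix(rnorm(f_in * f_out), f_in, f_out),
                     b = rnorm(f_out),
                     activation = sample(c("identity", "leaky_relu"), 1))
    })
    expect_equal(graph_conv_apply(X, g, params),
                 naive_graph_conv(X, g, params), tolerance = 1e-6)
  }
})

test_that("graph convolution edge behaviors", {
  # disconnected graph: neighbor term vanishes
  g <- baseline_graph("disconnected", L = 3L)
  X <- withr::with_seed(1L, matrix(rnorm(6), 3L, 2L))
  params <- withr::with_seed(2L, list(W_C = matrix(rnorm(4), 2, 2),
                                      W_N = matrix(rnorm(4), 2, 2),
                                      b = c(0.1, -0.2)))
  Z <- graph_conv_apply(X, g, params)
  expect_equal(Z, sweep(X %*% params$W_C, 2, params$b, "+"))
  # complete graph with identical node features: all outputs equal
  gc <- baseline_graph("complete", L = 4L)
  Xc <- matrix(rep(c(1, -1), each = 4), 4L, 2L)
  Zc <- graph_conv_apply(Xc, gc, params)
  expect_equal(Zc, Zc[rep(1, 4), ], ignore_attr = TRUE)
  expect_error(graph_conv_apply(X[, 1, drop = FALSE], g, params),
               "feature width")
})

test_that("build_model counts parameters and is seed-reproducible", {
  L <- 10L; Fw <- 40L
  lin <- build_model(model_spec("linear", seed = 3L), L, Fw)
  expect_equal(lin$n_params, L * Fw + 1)
  lin2 <- build_model(model_spec("linear", seed = 3L), L, Fw)
  expect_identical(lin$layers, lin2$layers)
  lin3 <- build_model(model_spec("linear", seed = 4L), L, Fw)
  expect_false(identical(lin$layers, lin3$layers))

  # valid convolution: flatten width implies L - k + 1 output positions
  k <- 4L; nf <- 8L
  cnn <- build_model(model_spec("seq_conv", kernel = k, filters = nf,
                                final_dense_width = 50L), L, Fw)
  desc <- model_describe(cnn)
  expect_equal(desc$kind[1], "seq_conv")
  expect_equal(desc$n_params[1], k * Fw * nf + nf)
  dense_idx <- which(desc$kind == "dense")[1]
  expect_equal(desc$n_params[dense_idx], (L - k + 1) * nf * 50 + 50)
  expect_error(build_model(model_spec("seq_conv", kernel = 11L), L, Fw),
               "too short")
  g <- baseline_graph("sequential", L = L)
  gcn <- build_model(model_spec("graph_conv", graph = g, filters = nf), L, Fw)
  expect_equal(model_describe(gcn)$n_params[1], 2 * Fw * nf + nf)
  expect_error(build_model(model_spec("graph_conv",
                                      graph = baseline_graph("complete",
                                                             L = 4L)),
                           L, Fw),
               "nodes")
  expect_error(model_spec("graph_conv"), "requires a structure graph")
})

test_that("prediction is deterministic, batch-consistent and shape-checked", {
  prob <- tiny_problem()
  g <- baseline_graph("sequential", L = prob$wt$length)
  for (spec in list(model_spec("linear"),
                    model_spec("fully_connected", hidden = 16L),
                    model_spec("seq_conv", filters = 4L, kernel = 3L,
                               final_dense_width = 20L),
                    model_spec("graph_conv", graph = g, filters = 4L,
                               final_dense_width = 20L))) {
    m <- build_model(spec, prob$wt$length, dim(prob$X)[3])
    p1 <- predict(m, prob$X[1:6, , ])
    p2 <- predict(m, prob$X[1:6, , ])
    expect_identical(p1, p2) # dropout off at prediction time
    single <- vapply(1:6, function(i) predict(m, prob$X[i, , ]), numeric(1))
    expect_equal(single, p1, tolerance = 1e-6)
    expect_true(all(is.finite(p1)))
  }
  m <- build_model(model_spec("linear"), 5L, 4L)
  expect_error(predict(m, prob$X), "does not match model")
})

test_that("linear model predictions are exactly additive", {
  prob <- tiny_problem()
  m <- build_model(model_spec("linear", seed = 9L), prob$wt$length,
                   dim(prob$X)[3])
  wt <- prob$wt; proj <- prob$proj
  f <- function(v) predict(m, encode_variant(v, wt, proj))
  f_wt <- f("")
  sub <- function(p, aa) paste0(wt$letters[p], p, aa)
  singles <- c(sub(1L, setdiff(aa_alphabet(), wt$letters[1])[1]),
               sub(4L, setdiff(aa_alphabet(), wt$letters[4])[2]),
               sub(9L, setdiff(aa_alphabet(), wt$letters[9])[3]))
  combos <- utils::combn(3L, 2L, simplify = FALSE)
  for (pair_idx in combos) {
    pair <- singles[pair_idx]
    expect_equal(f(paste(pair, collapse = ",")) - f_wt,
                 (f(pair[1]) - f_wt) + (f(pair[2]) - f_wt),
                 tolerance = 1e-6)
  }
})

test_that("graph_conv on the disconnected graph equals a kernel-1 sequence conv", {
  # per-position dense transform: with no neighbors the graph layer reduces
  # to W_C applied at each position, i.e. a width-1 convolution
  prob <- tiny_problem()
  L <- prob$wt$length; Fw <- dim(prob$X)[3]
  g <- baseline_graph("disconnected", L = L)
  gcn <- build_model(model_spec("graph_conv", graph = g, filters = 6L,
                                final_dense_width = 20L, seed = 5L), L, Fw)
  cnn <- build_model(model_spec("seq_conv", kernel = 1L, filters = 6L,
                                final_dense_width = 20L, seed = 5L), L, Fw)
  # transplant parameters: W_C -> conv W; shared head copied verbatim
  cnn$layers[[1]]$W <- gcn$layers[[1]]$W_C
  cnn$layers[[1]]$b <- gcn$layers[[1]]$b
  for (i in 3:length(gcn$layers)) {
    for (p in dms2func:::.param_names(gcn$layers[[i]]))
      cnn$layers[[i]][[p]] <- gcn$layers[[i]][[p]]
  }
  expect_equal(predict(cnn, prob$X[1:10, , ]), predict(gcn, prob$X[1:10, , ]),
               tolerance = 1e-10)
})

test_that("model JSON round trip preserves predictions", {
  prob <- tiny_problem()
  g <- random_graph(prob$wt$length, seed = 8L)
  g <- dms2func:::.new_structure_graph(g, "contact")
  m <- build_model(model_spec("graph_conv", graph = g, filters = 4L,
                              final_dense_width = 10L, seed = 2L),
                   prob$wt$length, dim(prob$X)[3])
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, prob$X[1:8, , ]), predict(m, prob$X[1:8, , ]),
               tolerance = 1e-12)
  ml <- build_model(model_spec("fully_connected", hidden = c(8L, 4L)),
                    prob$wt$length, dim(prob$X)[3])
  save_model(ml, path)
  expect_equal(predict(load_model(path), prob$X[1:4, , ]),
               predict(ml, prob$X[1:4, , ]), tolerance = 1e-12)
})
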