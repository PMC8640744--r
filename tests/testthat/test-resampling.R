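test_that("count tables validate and round-trip as TSV", {
  t <- count_table(c("", "M1C", "T2A"), c(100, 10, 4), c(90, 20, 1))
  expect_s3_class(t, "read_count_table")
  expect_error(count_table(c("a", "a"), c(1, 1), c(1, 1)), "unique")
  expect_error(count_table("a", -1, 1), "nonnegative")
  expect_error(count_table("a", 1.5, 1), "nonnegative")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(t, path)
  t2 <- read_counts(path)
  expect_equal(as.data.frame(t2), as.data.frame(t))
})

test_that("filter_counts applies the both-pools threshold", {
  t <- count_table(c("", "a1", "a2", "a3"),
                   c(100, 4, 50, 7), c(90, 60, 0, 9))
  # fewer than five reads in the input pool: removed
  expect_equal(filter_counts(t, 5)$variant, c("", "a3"))
  # zero reads in either pool: removed at threshold 1
  expect_equal(filter_counts(t, 1)$variant, c("", "a1", "a3"))
  all_pass <- count_table(c("", "x"), c(9, 9), c(9, 9))
  expect_equal(nrow(filter_counts(all_pass, 5)), 2L)
})

test_that("enrichment scores are wild-type-normalized log ratios", {
  t <- count_table(c("", "v1", "v2"), c(10, 10, 10), c(10, 20, 10))
  s <- enrichment_score(t, wt_id = "")
  expect_equal(s$score[1], 0) # wild type scores zero by construction
  expect_equal(s$score[3], 0) # same counts as wild type
  expect_equal(s$score[2], log(20.5 / 10.5) - log(10.5 / 10.5),
               tolerance = 1e-12)
  expect_equal(s$score[2], 0.6690, tolerance = 1e-4)
  expect_error(enrichment_score(count_table("v", 1, 1), ""), "missing")
})

test_that("resampling conserves the read budget exactly", {
  base <- withr::with_seed(2L,
    count_table(c("", paste0("v", 1:30)),
                c(500, rpois(30, 50) + 1), c(480, rpois(30, 40) + 1)))
  for (s in 1:5) {
    rs <- resample_dataset(base, library_size = 10L, total_reads = 777L,
                           seed = s)
    expect_equal(sum(rs$count_input) + sum(rs$count_selected), 777)
  }
  one <- resample_dataset(base, 1L, 100L, seed = 3L)
  expect_equal(sum(one$count_input) + sum(one$count_selected), 100)
  # include= forces the wild type into the library
  rs <- resample_dataset(base, 3L, 100L, seed = 9L, include = "")
  expect_true("" %in% rs$variant)
})

test_that("sampled frequencies are unbiased for the base frequencies", {
  base <- count_table(paste0("v", 1:5), c(10, 20, 30, 40, 100),
                      c(100, 40, 30, 20, 10))
  freq <- sapply(1:200, function(s) {
    rs <- resample_dataset(base, 5L, 400L, seed = s)
    rs$count_input[match(base$variant, rs$variant)] / sum(rs$count_input)
  })
  p <- base$count_input / sum(base$count_input)
  se <- sqrt(p * (1 - p) / (0.5 * 400)) / sqrt(200)
  expect_true(all(abs(rowMeans(freq) - p) < 3 * se + 1e-3))
})

test_that("scores are stable under uniform scaling of both pools", {
  withr::with_seed(5L, {
    inp <- rpois(20, 60) + 20
    sel <- rpois(20, 60) + 20
  })
  t1 <- count_table(c("", paste0("v", 1:19)), inp, sel)
  t10 <- count_table(c("", paste0("v", 1:19)), inp * 10, sel * 10)
  s1 <- enrichment_score(t1)$score
  s10 <- enrichment_score(t10)$score
  expect_equal(s1, s10, tolerance = 0.05) # exact up to the 0.5 pseudocount
})

test_that("run_grid fills cells, excludes starved ones and counts datasets", {
  spec <- landscape_spec(L = 10L, seed = 41L, n_epistatic = 0L,
                         noise_sd = 0.05)
  ds <- sample_dataset(spec, n_variants = 250L, max_mutations = 2L,
                       seed = 42L)
  counts <- simulate_read_counts(ds, total_reads = 120000L,
                                 selection_strength = 2, seed = 43L)
  base <- filter_counts(counts, 1L)
  test_idx <- 2:31
  truth <- dms_dataset(spec$wild_type, ds$data$variant[test_idx],
                       ds$data$score[test_idx])
  proj <- test_proj()
  grid <- run_grid(base, truth, spec$wild_type, proj,
                   model_spec("linear", seed = 1L),
                   library_sizes = 160L, read_budgets = c(30L, 60000L),
                   replicates = 5L,
                   config = training_config(lr = 0.01, batch_size = 32L),
                   seed = 44L)
  expect_equal(nrow(grid), 2L)
  expect_equal(attr(grid, "n_datasets"), 10L) # cells x 5 replicates
  starved <- grid[grid$total_reads == 30L, ]
  expect_true(starved$excluded) # < 25 observed variants in some replicate
  expect_true(is.na(starved$mean_pearson))
  rich <- grid[grid$total_reads == 60000L, ]
  expect_false(rich$excluded)
  expect_gt(rich$mean_pearson, 0.2)
})
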