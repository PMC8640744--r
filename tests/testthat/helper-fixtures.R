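# Shared fixtures, all built in code at test time.

toy_wt <- function() wild_type("toy", "MTEYKAVLAG")

# property projection fitted once per session from the packaged synthetic
# property table
test_proj <- local({
  proj <- NULL
  function(d = 19L) {
    if (is.null(proj) || proj$d != d) {
      props <- read_property_matrix(
        system.file("extdata", "aa_properties_synthetic.csv",
                    package = "dms2func"))
      proj <<- fit_property_projection(props, d)
    }
    proj
  }
})

test_props <- function() {
  read_property_matrix(
    system.file("extdata", "aa_properties_synthetic.csv",
                package = "dms2func"))
}

# small noiseless additive landscape + dataset + encodings, for fast model
# tests
tiny_problem <- function(L = 12L, n = 150L, seed = 7L, noise_sd = 0,
                         n_epistatic = 0L, max_mutations = 2L) {
  spec <- landscape_spec(L = L, seed = seed, noise_sd = noise_sd,
                         n_epistatic = n_epistatic)
  ds <- sample_dataset(spec, n_variants = n, max_mutations = max_mutations,
                       seed = seed + 1L)
  proj <- test_proj()
  X <- encode_variants(ds, spec$wild_type, proj)
  list(spec = spec, ds = ds, proj = proj, X = X, wt = spec$wild_type,
       y = ds$data$score)
}

# random igraph structure graph on n nodes (Erdos-Renyi, seeded)
random_graph <- function(n, p = 0.4, seed = 1L) {
  withr::with_seed(seed, {
    A <- matrix(stats::runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  })
}

# independent oracle for the graph convolution: per-node loop over
# neighbors, no matrix tricks
naive_graph_conv <- function(X, g, params) {
  n_f <- ncol(params$W_C)
  Z <- matrix(0, nrow(X), n_f)
  for (i in seq_len(nrow(X))) {
    z <- as.numeric(X[i, , drop = FALSE] %*% params$W_C)
    nb <- as.integer(igraph::neighbors(g, i))
    if (length(nb) > 0L) {
      acc <- numeric(n_f)
      for (j in nb) acc <- acc + as.numeric(X[j, , drop = FALSE] %*% params$W_N)
      z <- z + acc / length(nb)
    }
    z <- z + params$b
    if (!is.null(params$activation) && params$activation == "leaky_relu")
      z <- ifelse(z < 0, 0.2 * z, z)
    Z[i, ] <- z
  }
  Z
}

# minimal synthetic PDB text for coordinate-parsing tests
synthetic_pdb_lines <- function(seq1, xyz, chain = "A") {
  aa3 <- setNames(names(dms2func:::AA3TO1), dms2func:::AA3TO1)
  lines <- character(0)
  serial <- 1L
  for (i in seq_along(seq1)) {
    res <- aa3[[seq1[i]]]
    atoms <- if (seq1[i] == "G") "CA" else c("CA", "CB")
    for (at in atoms) {
      shift <- if (at == "CA") 0.3 else 0 # CB carries the tested coordinate
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, at, res, chain, i,
        xyz[i, 1] + shift, xyz[i, 2], xyz[i, 3]))
      serial <- serial + 1L
    }
  }
  lines
}
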