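# Residue contact graphs for the graph convolutional network, plus the four
# misspecified baseline graphs (shuffled, disconnected, sequential, complete)
# used to probe how much real structure contributes to model accuracy.
# Graphs are igraph objects with a "kind" attribute; node count always equals
# the wild-type length.

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

#' Extract per-residue coordinates from a PDB file
#'
#' Reads ATOM records of one chain and returns one 3-D coordinate per residue:
#' the beta-carbon (CB), falling back to the alpha-carbon (CA) for glycine or
#' when CB is absent. Alternate locations other than blank/'A' and
#' non-standard residues are skipped. There is no maintained PDB parser among
#' this package's dependencies, so a minimal fixed-column ATOM-record reader
#' is implemented here.
#'
#' @param path PDB file path.
#' @param chain Chain identifier (default `"A"`).
#' @param wt Optional [wild_type()]; if given, the residue sequence read from
#'   the PDB must match `wt$sequence` exactly, otherwise an error is raised
#'   (no silent renumbering).
#' @return An object of class `residue_coords`: list with `xyz` (L x 3 matrix,
#'   angstroms), `sequence` and `resid` (author residue numbers).
#' @export
read_residue_coords <- function(path, chain = "A", wt = NULL) {
  lines <- readLines(path)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (length(atoms) == 0L) stop("no ATOM records in ", path)
  fld <- function(x, a, b) trimws(substr(x, a, b))
  rec <- data.frame(
    name = fld(atoms, 13, 16), alt = fld(atoms, 17, 17),
    res = fld(atoms, 18, 20), chain = fld(atoms, 22, 22),
    resseq = as.integer(fld(atoms, 23, 26)),
    x = as.numeric(fld(atoms, 31, 38)),
    y = as.numeric(fld(atoms, 39, 46)),
    z = as.numeric(fld(atoms, 47, 54)),
    stringsAsFactors = FALSE)
  rec <- rec[rec$chain == chain & rec$alt %in% c("", "A") &
               rec$res %in% names(AA3TO1), ]
  if (nrow(rec) == 0L) stop("no standard-residue ATOM records for chain ",
                            chain, " in ", path)
  resids <- unique(rec$resseq)
  xyz <- matrix(NA_real_, length(resids), 3L)
  seq1 <- character(length(resids))
  for (i in seq_along(resids)) {
    r <- rec[rec$resseq == resids[i], ]
    seq1[i] <- AA3TO1[[r$res[1]]]
    hit <- r[r$name == "CB", ]
    if (nrow(hit) == 0L) hit <- r[r$name == "CA", ]
    if (nrow(hit) == 0L) stop("residue ", resids[i], " has neither CB nor CA")
    xyz[i, ] <- as.numeric(hit[1, c("x", "y", "z")])
  }
  if (any(!is.finite(xyz)))
    stop("missing coordinates for residue(s): ",
         paste(resids[!stats::complete.cases(xyz)], collapse = ", "))
  if (!is.null(wt)) {
    stopifnot(inherits(wt, "wild_type"))
    got <- paste(seq1, collapse = "")
    if (!identical(got, wt$sequence))
      stop("PDB chain sequence does not match wild type:\n  pdb: ", got,
           "\n  wt:  ", wt$sequence)
  }
  structure(list(xyz = xyz, sequence = paste(seq1, collapse = ""),
                 resid = resids),
            class = "residue_coords")
}

#' Construct residue coordinates directly from a matrix
#'
#' Convenience constructor for synthetic fixtures and tests.
#'
#' @param xyz L x 3 numeric matrix of coordinates in angstroms.
#' @param sequence Optional sequence string of length L.
#' @return A `residue_coords` object.
#' @export
residue_coords <- function(xyz, sequence = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(is.numeric(xyz), ncol(xyz) == 3L, nrow(xyz) >= 1L)
  if (any(!is.finite(xyz))) {
    bad <- which(!stats::complete.cases(xyz))
    stop("non-finite coordinates for residue(s): ", paste(bad, collapse = ", "))
  }
  structure(list(xyz = xyz,
                 sequence = if (is.null(sequence)) NULL else sequence,
                 resid = seq_len(nrow(xyz))),
            class = "residue_coords")
}

#' Pairwise residue distance matrix
#'
#' @param coords A `residue_coords` object.
#' @return Symmetric L x L matrix of Euclidean distances in angstroms, zero
#'   diagonal.
#' @export
residue_distance_matrix <- function(coords) {
  stopifnot(inherits(coords, "residue_coords"))
  as.matrix(stats::dist(coords$xyz))
}

.new_structure_graph <- function(g, kind) {
  igraph::graph_attr(g, "kind") <- kind
  g
}

#' Build the residue contact graph
#'
#' Nodes are residues; an undirected edge joins residues whose distance is at
#' most `threshold` angstroms (closed comparison, self-pairs excluded). The
#' distance threshold is a model hyperparameter typically swept over 4-10 A.
#'
#' @param coords A `residue_coords` object.
#' @param threshold Contact distance threshold in angstroms.
#' @return An undirected igraph with `L` vertices and graph attribute
#'   `kind = "contact"`.
#' @export
build_contact_graph <- function(coords, threshold) {
  stopifnot(threshold > 0)
  D <- residue_distance_matrix(coords)
  A <- (D <= threshold)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  .new_structure_graph(g, "contact")
}

#' Baseline control graphs
#'
#' The four misspecified graphs used to test whether structural information in
#' the contact graph matters: `"shuffled"` (the reference graph under a seeded
#' node-label permutation), `"disconnected"` (no edges), `"sequential"` (edges
#' between chain neighbors only) and `"complete"` (all pairs).
#'
#' @param kind One of `"shuffled"`, `"disconnected"`, `"sequential"`,
#'   `"complete"`.
#' @param L Node count (wild-type length). Ignored for `"shuffled"`, which
#'   takes its size from `reference`.
#' @param seed Integer seed for the shuffled permutation.
#' @param reference Reference graph, required for `"shuffled"`.
#' @return An undirected igraph with graph attribute `kind`.
#' @export
baseline_graph <- function(kind = c("shuffled", "disconnected", "sequential",
                                    "complete"),
                           L = NULL, seed = 1L, reference = NULL) {
  kind <- match.arg(kind)
  if (kind == "shuffled") {
    if (is.null(reference))
      stop("shuffled baseline requires a reference graph")
    n <- igraph::vcount(reference)
    perm <- withr::with_seed(seed, sample.int(n))
    g <- igraph::permute(reference, perm)
    return(.new_structure_graph(g, "shuffled"))
  }
  stopifnot(!is.null(L), L >= 1L)
  g <- switch(kind,
    disconnected = igraph::make_empty_graph(n = L, directed = FALSE),
    sequential = if (L == 1L) igraph::make_empty_graph(n = 1L, directed = FALSE)
                 else igraph::make_graph(rbind(seq_len(L - 1L), seq_len(L)[-1]),
                                         n = L, directed = FALSE),
    complete = igraph::make_full_graph(L, directed = FALSE))
  .new_structure_graph(g, kind)
}

#' Row-normalized adjacency matrix of a structure graph
#'
#' Used by the graph convolution operator: row i holds `1/|N_i|` at i's
#' neighbors, and is all-zero when node i has no neighbors (the neighbor term
#' of the convolution then vanishes).
#'
#' @param g An igraph structure graph.
#' @return Dense L x L numeric matrix.
#' @export
graph_neighbor_weights <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  deg <- rowSums(A)
  A[deg > 0, ] <- A[deg > 0, , drop = FALSE] / deg[deg > 0]
  A
}

#' Read / write a structure graph as an edge-list text file
#'
#' Plain-text persistence: a header line `# dms2func graph L=<n> kind=<kind>`
#' followed by one `i<TAB>j` pair per edge (1-based, i < j).
#'
#' @param g An igraph structure graph.
#' @param path Output path.
#' @return For `read_structure_graph`, an igraph structure graph.
#' @export
write_structure_graph <- function(g, path) {
  e <- igraph::as_edgelist(g)
  mode(e) <- "integer"
  if (nrow(e) > 0L) e <- t(apply(e, 1L, sort))
  kind <- igraph::graph_attr(g, "kind")
  if (is.null(kind)) kind <- "contact"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dms2func graph L=%d kind=%s",
                     igraph::vcount(g), kind), con)
  if (nrow(e) > 0L)
    writeLines(paste(e[, 1], e[, 2], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_structure_graph
#' @export
read_structure_graph <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr, regexec("L=([0-9]+) kind=([a-z]+)", hdr))[[1]]
  if (length(m) != 3L) stop("malformed graph header in ", path)
  L <- as.integer(m[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) > 0L) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    edges <- rbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
    g <- igraph::make_graph(edges, n = L, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = L, directed = FALSE)
  }
  .new_structure_graph(g, m[3])
}
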