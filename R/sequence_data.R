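# 20 standard amino acids in fixed alphabetical order, then the stop symbol.
# This ordering defines one-hot columns everywhere in the package.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA21 <- c(AA20, "*")

#' Standard amino-acid alphabets
#'
#' `aa_alphabet()` returns the 20 standard amino-acid one-letter codes in the
#' fixed order used for all one-hot encodings in this package;
#' `aa_alphabet_stop()` appends the stop symbol `"*"` as the 21st letter.
#'
#' @return Character vector of single letters.
#' @export
aa_alphabet <- function() AA20

#' @rdname aa_alphabet
#' @export
aa_alphabet_stop <- function() AA21

#' Construct a wild-type reference sequence
#'
#' A wild type anchors variant notation: substitution positions are 1-based
#' indices into this sequence, and the wild-type letter in a substitution code
#' must match it.
#'
#' @param id Character label for the protein (e.g. `"GB1"`).
#' @param sequence Character scalar over the 20 standard amino-acid letters.
#' @return An object of class `wild_type` with fields `id`, `sequence`,
#'   `length` and `letters` (the sequence split into single characters).
#' @examples
#' wt <- wild_type("toy", "MTAYKLV")
#' wt$length
#' @export
wild_type <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  letters <- strsplit(sequence, "")[[1]]
  if (length(letters) < 1L)
    stop("wild-type sequence must have length >= 1")
  bad <- setdiff(unique(letters), AA20)
  if (length(bad) > 0L)
    stop("wild-type sequence contains non-standard letters: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence,
                 length = length(letters), letters = letters),
            class = "wild_type")
}

#' @export
print.wild_type <- function(x, ...) {
  cat(sprintf("<wild_type> %s (L = %d)\n%s\n", x$id, x$length, x$sequence))
  invisible(x)
}

#' Read a wild-type sequence from a FASTA file
#'
#' Uses Biostrings to parse the FASTA; the first record is taken as the wild
#' type and its header (up to the first whitespace) as the id.
#'
#' @param path Path to a FASTA file containing at least one amino-acid record.
#' @return A [wild_type()] object.
#' @export
read_wild_type <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required to read FASTA files")
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1L) stop("no sequences found in ", path)
  id <- strsplit(names(set)[1], "\\s+")[[1]][1]
  wild_type(id, as.character(set[[1]]))
}

#' Write a wild type to FASTA
#'
#' @param wt A [wild_type()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wild_type <- function(wt, path) {
  stopifnot(inherits(wt, "wild_type"))
  writeLines(c(paste0(">", wt$id), wt$sequence), path)
  invisible(path)
}

# Parse raw substitution codes ("E19Q") into a data.frame without validation.
# Returns columns wt_aa, pos, mut_aa in input order.
.split_codes <- function(codes) {
  ok <- grepl("^[A-Z][0-9]+[A-Z*]$", codes)
  if (!all(ok))
    stop("malformed substitution code(s): ",
         paste(codes[!ok], collapse = ", "))
  n <- nchar(codes)
  data.frame(wt_aa = substr(codes, 1L, 1L),
             pos = as.integer(substr(codes, 2L, n - 1L)),
             mut_aa = substr(codes, n, n),
             stringsAsFactors = FALSE)
}

#' Parse a variant substitution string
#'
#' Variants are written as comma-separated substitution codes in the usual
#' mutation notation, e.g. `"E19Q,A24Y"` for the double mutant carrying E19Q
#' and A24Y. The empty string denotes the wild type itself. Positions are
#' 1-based; the stop symbol `"*"` is allowed as a mutant (never wild-type)
#' letter.
#'
#' @param text Character scalar of comma-separated substitution codes
#'   (possibly `""`).
#' @param wt A [wild_type()] object the codes are validated against.
#' @return An object of class `dms_variant`: a list with integer vector `pos`
#'   (ascending), character vectors `wt_aa` and `mut_aa`, and `n_mut`.
#' @examples
#' wt <- wild_type("toy", "MTEYKAV")
#' v <- parse_variant("E3Q,A6Y", wt)
#' v$n_mut
#' @export
parse_variant <- function(text, wt) {
  stopifnot(inherits(wt, "wild_type"),
            is.character(text), length(text) == 1L, !is.na(text))
  text <- gsub("\\s+", "", text)
  if (identical(text, "")) {
    return(structure(list(pos = integer(0), wt_aa = character(0),
                          mut_aa = character(0), n_mut = 0L),
                     class = "dms_variant"))
  }
  d <- .split_codes(strsplit(text, ",", fixed = TRUE)[[1]])
  if (any(d$pos < 1L | d$pos > wt$length))
    stop("position out of range [1, ", wt$length, "]: ",
         paste(d$pos[d$pos < 1L | d$pos > wt$length], collapse = ", "))
  if (anyDuplicated(d$pos))
    stop("duplicate substitution position(s): ",
         paste(unique(d$pos[duplicated(d$pos)]), collapse = ", "))
  mism <- d$wt_aa != wt$letters[d$pos]
  if (any(mism))
    stop("wt mismatch at position ", paste(d$pos[mism], collapse = ", "),
         ": expected ", paste(wt$letters[d$pos[mism]], collapse = ", "),
         ", code says ", paste(d$wt_aa[mism], collapse = ", "))
  if (any(d$mut_aa == d$wt_aa))
    stop("mutant letter equals wild-type letter at position ",
         paste(d$pos[d$mut_aa == d$wt_aa], collapse = ", "))
  if (any(!d$mut_aa %in% AA21))
    stop("unknown mutant letter(s): ",
         paste(setdiff(d$mut_aa, AA21), collapse = ", "))
  o <- order(d$pos)
  structure(list(pos = d$pos[o], wt_aa = d$wt_aa[o], mut_aa = d$mut_aa[o],
                 n_mut = nrow(d)),
            class = "dms_variant")
}

#' Format a variant as its canonical substitution string
#'
#' The canonical form lists substitutions in ascending position order, so
#' `format_variant(parse_variant(s, wt))` is the identity on canonical
#' strings.
#'
#' @param v A `dms_variant`.
#' @return Character scalar (empty for the wild type).
#' @export
format_variant <- function(v) {
  stopifnot(inherits(v, "dms_variant"))
  if (v$n_mut == 0L) return("")
  paste0(v$wt_aa, v$pos, v$mut_aa, collapse = ",")
}

#' @export
print.dms_variant <- function(x, ...) {
  cat(sprintf("<dms_variant> %s (%d substitution%s)\n",
              if (x$n_mut) format_variant(x) else "(wild type)",
              x$n_mut, if (x$n_mut == 1L) "" else "s"))
  invisible(x)
}

#' Apply a variant to its wild type
#'
#' @param v A `dms_variant` valid against `wt`.
#' @param wt A [wild_type()] object.
#' @return The full mutated sequence as a character scalar; it differs from
#'   `wt$sequence` at exactly `v$n_mut` positions.
#' @export
apply_variant <- function(v, wt) {
  stopifnot(inherits(v, "dms_variant"), inherits(wt, "wild_type"))
  if (v$n_mut == 0L) return(wt$sequence)
  letters <- wt$letters
  letters[v$pos] <- v$mut_aa
  paste(letters, collapse = "")
}

#' Recover a variant from a full mutated sequence
#'
#' Inverse of [apply_variant()]: diffs `seq` against the wild type and returns
#' the corresponding substitution set.
#'
#' @param seq Character scalar, same length as the wild type.
#' @param wt A [wild_type()] object.
#' @return A `dms_variant`.
#' @export
variant_from_sequence <- function(seq, wt) {
  stopifnot(inherits(wt, "wild_type"), is.character(seq), length(seq) == 1L)
  s <- strsplit(seq, "")[[1]]
  if (length(s) != wt$length)
    stop("sequence length ", length(s), " != wild-type length ", wt$length)
  pos <- which(s != wt$letters)
  structure(list(pos = pos, wt_aa = wt$letters[pos], mut_aa = s[pos],
                 n_mut = length(pos)),
            class = "dms_variant")
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of positions at which `a` and `b` differ.
#' @examples
#' hamming_distance("ACDE", "YCDF")
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Construct a DMS dataset of variants with functional scores
#'
#' @param wt A [wild_type()] object.
#' @param variants Character vector of substitution strings (see
#'   [parse_variant()]); each is validated and canonicalized.
#' @param scores Numeric vector of finite functional scores, same length.
#' @return An object of class `dms_dataset`: list with `wild_type` and a
#'   data.frame `data` with columns `variant` (canonical string) and `score`.
#' @export
dms_dataset <- function(wt, variants, scores) {
  stopifnot(inherits(wt, "wild_type"),
            is.character(variants), is.numeric(scores),
            length(variants) == length(scores))
  if (any(!is.finite(scores)))
    stop("non-finite score(s) at row(s): ",
         paste(utils::head(which(!is.finite(scores)), 5L), collapse = ", "))
  canon <- vapply(variants, function(s) format_variant(parse_variant(s, wt)),
                  character(1), USE.NAMES = FALSE)
  structure(list(wild_type = wt,
                 data = data.frame(variant = canon, score = as.numeric(scores),
                                   stringsAsFactors = FALSE)),
            class = "dms_dataset")
}

#' @export
print.dms_dataset <- function(x, ...) {
  cat(sprintf("<dms_dataset> %s: %d variants (L = %d)\n",
              x$wild_type$id, nrow(x$data), x$wild_type$length))
  invisible(x)
}

#' Number of variants in a dataset
#' @param ds A `dms_dataset`.
#' @return Integer.
#' @export
n_variants <- function(ds) {
  stopifnot(inherits(ds, "dms_dataset"))
  nrow(ds$data)
}

#' Per-variant mutation counts
#' @param ds A `dms_dataset`.
#' @return Integer vector (0 for the wild-type row).
#' @export
mutation_counts <- function(ds) {
  stopifnot(inherits(ds, "dms_dataset"))
  v <- ds$data$variant
  ifelse(v == "", 0L, lengths(strsplit(v, ",", fixed = TRUE)))
}

#' Read / write DMS datasets as TSV
#'
#' The on-disk format is a tab-separated file with a header and columns
#' `variant` (comma-separated substitution codes, empty string = wild type)
#' and `score`. Round-tripping through [write_dataset()] and
#' [read_dataset()] is lossless.
#'
#' @param path File path.
#' @param wt A [wild_type()] the variants are validated against.
#' @return For `read_dataset`, a [dms_dataset()].
#' @export
read_dataset <- function(path, wt) {
  stopifnot(inherits(wt, "wild_type"))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!all(c("variant", "score") %in% header))
    stop("dataset file ", path, " must have columns 'variant' and 'score'")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(variant = "character"),
                           na.strings = NULL)
  scores <- suppressWarnings(as.numeric(tab$score))
  if (any(is.na(scores)))
    stop("non-numeric score at line ",
         paste(which(is.na(scores)) + 1L, collapse = ", "), " of ", path)
  # validate row by row so errors carry the offending line number
  for (i in seq_along(tab$variant)) {
    res <- tryCatch(parse_variant(tab$variant[i], wt), error = identity)
    if (inherits(res, "error"))
      stop("line ", i + 1L, " of ", path, ": ", conditionMessage(res))
    tab$variant[i] <- format_variant(res)
  }
  dms_dataset(wt, tab$variant, scores)
}

#' @rdname read_dataset
#' @param ds A `dms_dataset` to serialize.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "dms_dataset"))
  utils::write.table(ds$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subset a dataset by variant indices
#'
#' @param ds A `dms_dataset`.
#' @param idx Integer vector of row indices.
#' @return A `dms_dataset` with the selected rows, in the given order.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "dms_dataset"))
  out <- ds
  out$data <- ds$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
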