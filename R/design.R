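# Model-guided sequence design: random-restart hill climbing over the set of
# sequences at a fixed Hamming distance n from the wild type, maximizing the
# minimum predicted score across an ensemble of trained models. The
# conservative min-ensemble objective only rewards sequences that every model
# agrees are good.

#' Minimum-over-ensemble design objective
#'
#' @param variants Character vector of substitution strings (or a single
#'   `dms_variant`).
#' @param ensemble Non-empty list of `dms_model` objects sharing `L` and
#'   input width.
#' @param wt A [wild_type()] object.
#' @param proj A `property_projection`.
#' @return Numeric vector: for each variant, the minimum predicted score over
#'   the ensemble. The per-model predictions are attached as the
#'   `"per_model"` attribute (a `n x n_models` matrix).
#' @export
ensemble_min_objective <- function(variants, ensemble, wt, proj) {
  stopifnot(is.list(ensemble), length(ensemble) >= 1L)
  if (inherits(variants, "dms_variant")) variants <- format_variant(variants)
  X <- encode_variants(variants, wt, proj)
  per_model <- vapply(ensemble, function(m) predict(m, X),
                      numeric(length(variants)))
  per_model <- matrix(per_model, nrow = length(variants),
                      dimnames = list(NULL, names(ensemble)))
  obj <- apply(per_model, 1L, min)
  attr(obj, "per_model") <- per_model
  obj
}

#' Random variant at exact Hamming distance n
#'
#' Picks `n` distinct positions uniformly and a non-wild-type letter at each.
#'
#' @param wt A [wild_type()] object.
#' @param n Mutation count, `0 <= n <= L`.
#' @param seed Integer seed.
#' @param alphabet Candidate letters (default the 20 standard amino acids;
#'   stop codons are excluded from design).
#' @return A `dms_variant` with exactly `n` substitutions.
#' @export
random_n_mutant <- function(wt, n, seed = 1L, alphabet = aa_alphabet()) {
  stopifnot(inherits(wt, "wild_type"), n >= 0L, n <= wt$length)
  if (n == 0L) return(parse_variant("", wt))
  withr::with_seed(seed, {
    pos <- sort(sample.int(wt$length, n))
    mut <- vapply(pos, function(p)
      sample(setdiff(alphabet, wt$letters[p]), 1L), character(1))
  })
  parse_variant(paste0(wt$letters[pos], pos, mut, collapse = ","), wt)
}

#' Mutation-exchange neighborhood at fixed distance
#'
#' All variants reachable by removing one current substitution and adding one
#' substitution at any position left unmutated by the removal (including
#' re-mutating the vacated position to a different letter). Every neighbor is
#' at Hamming distance exactly `n` from the wild type, and the variant is not
#' its own neighbor. Neighbors are ordered deterministically: by removed
#' substitution (ascending position), then by added position and letter.
#'
#' @param v A `dms_variant` with `n >= 1` substitutions.
#' @param wt A [wild_type()] object.
#' @param alphabet Candidate letters for the added substitution.
#' @return Character vector of canonical substitution strings (no
#'   duplicates).
#' @export
neighborhood <- function(v, wt, alphabet = aa_alphabet()) {
  stopifnot(inherits(v, "dms_variant"), inherits(wt, "wild_type"))
  if (v$n_mut == 0L) return(character(0))
  out <- vector("list", v$n_mut)
  for (i in seq_len(v$n_mut)) {
    keep <- setdiff(seq_len(v$n_mut), i)
    free_pos <- setdiff(seq_len(wt$length), v$pos[keep])
    cand_pos <- rep(free_pos, each = length(alphabet))
    cand_aa <- rep(alphabet, times = length(free_pos))
    ok <- cand_aa != wt$letters[cand_pos] &
      !(cand_pos == v$pos[i] & cand_aa == v$mut_aa[i])
    cand_pos <- cand_pos[ok]
    cand_aa <- cand_aa[ok]
    # canonical string: merge kept substitutions with the new one, sorted
    kp <- v$pos[keep]
    km <- v$mut_aa[keep]
    strs <- vapply(seq_along(cand_pos), function(j) {
      pos <- c(kp, cand_pos[j])
      mut <- c(km, cand_aa[j])
      o <- order(pos)
      paste0(wt$letters[pos[o]], pos[o], mut[o], collapse = ",")
    }, character(1))
    out[[i]] <- strs
  }
  unlist(out)
}

#' Ensemble-guided hill climbing at fixed mutation distance
#'
#' Runs `restarts` independent hill-climbing searches, each initialized at a
#' random `n`-mutant and greedily moving to the mutation-exchange neighbor
#' with the highest min-ensemble objective until no neighbor strictly
#' improves. The best local optimum over all restarts is returned. Given the
#' seed, the whole procedure is reproducible.
#'
#' @param ensemble Non-empty list of trained `dms_model`s.
#' @param wt A [wild_type()] object.
#' @param proj A `property_projection`.
#' @param n Mutation count of the designs (fixed throughout the search).
#' @param restarts Number of random initializations (default 10).
#' @param seed Integer seed.
#' @param alphabet Design alphabet (default the 20 standard amino acids).
#' @return An object of class `design_result`: list with `variant` (canonical
#'   substitution string), `sequence`, `objective`, `per_model` (named
#'   per-model predictions of the best design), `restart` (index of the
#'   winning restart) and `trajectories` (list of per-restart objective
#'   sequences, each strictly increasing).
#' @export
hill_climb <- function(ensemble, wt, proj, n, restarts = 10L, seed = 1L,
                       alphabet = aa_alphabet()) {
  stopifnot(n >= 1L, n <= wt$length, restarts >= 1L)
  best <- NULL
  trajectories <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    v <- random_n_mutant(wt, n, seed = seed + r - 1L, alphabet = alphabet)
    cur <- format_variant(v)
    cur_obj <- as.numeric(ensemble_min_objective(cur, ensemble, wt, proj))
    traj <- cur_obj
    repeat {
      nb <- neighborhood(v, wt, alphabet)
      obj <- ensemble_min_objective(nb, ensemble, wt, proj)
      k <- which.max(obj)
      if (obj[k] <= cur_obj) break
      cur <- nb[k]
      cur_obj <- obj[k]
      v <- parse_variant(cur, wt)
      traj <- c(traj, cur_obj)
    }
    trajectories[[r]] <- traj
    if (is.null(best) || cur_obj > best$objective) {
      final_obj <- ensemble_min_objective(cur, ensemble, wt, proj)
      best <- list(variant = cur, objective = cur_obj,
                   per_model = drop(attr(final_obj, "per_model")),
                   restart = r)
    }
  }
  structure(list(variant = best$variant,
                 sequence = apply_variant(parse_variant(best$variant, wt), wt),
                 objective = best$objective,
                 per_model = best$per_model,
                 restart = best$restart,
                 n = as.integer(n),
                 trajectories = trajectories),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> n = %d, objective %.4f (restart %d)\n%s\n",
              x$n, x$objective, x$restart, x$variant))
  invisible(x)
}

#' Exhaustively find the best n-mutant (small instances only)
#'
#' Brute-force reference for [hill_climb()]: enumerates every sequence at
#' Hamming distance exactly `n` from the wild type and returns the one with
#' the highest min-ensemble objective. The search space has
#' `choose(L, n) * (|alphabet|-1)^n` elements, so this is only feasible for
#' toy problems.
#'
#' @inheritParams hill_climb
#' @return List with `variant`, `objective`.
#' @export
exhaustive_best_n_mutant <- function(ensemble, wt, proj, n,
                                     alphabet = aa_alphabet()) {
  stopifnot(n >= 1L, n <= wt$length)
  pos_sets <- utils::combn(wt$length, n, simplify = FALSE)
  best <- list(variant = NULL, objective = -Inf)
  for (ps in pos_sets) {
    letter_opts <- lapply(ps, function(p) setdiff(alphabet, wt$letters[p]))
    combos <- expand.grid(letter_opts, stringsAsFactors = FALSE)
    strs <- apply(combos, 1L, function(row)
      paste0(wt$letters[ps], ps, row, collapse = ","))
    obj <- ensemble_min_objective(strs, ensemble, wt, proj)
    k <- which.max(obj)
    if (obj[k] > best$objective)
      best <- list(variant = strs[k], objective = as.numeric(obj[k]))
  }
  best
}
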