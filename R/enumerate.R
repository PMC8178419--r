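#' Enumerate the full combinatorial triple space
#'
#' All `L^3` residue triples over an alphabet of `L` letters, in
#' lexicographic order of the alphabet (position 1 varies slowest). For the
#' canonical 20-letter alphabet this is the 8000-member space of a
#' three-position site-saturation library.
#'
#' @param alphabet Letters to enumerate over; default [aa_alphabet()].
#' @return Character matrix, `L^3` x 3.
#' @export
#' @examples
#' nrow(enumerate_triples())  # 8000
enumerate_triples <- function(alphabet = aa_alphabet()) {
  L <- length(alphabet)
  m <- cbind(
    pos1 = rep(alphabet, each = L * L),
    pos2 = rep(rep(alphabet, each = L), times = L),
    pos3 = rep(alphabet, times = L * L)
  )
  m
}

#' Enumerate unobserved candidate triples
#'
#' The in silico synthesis step: all triples of the combinatorial space not
#' present in the observed screen, in lexicographic alphabet order. With 214
#' distinct observed triples this yields 8000 - 214 = 7786 candidates. The
#' wild-type triple is excluded only if it appears in the observed set.
#'
#' @param observed Observed triples in any form accepted by [as_triples()],
#'   or `NULL` for none.
#' @param alphabet Alphabet defining the space.
#' @return Character matrix of candidate triples.
#' @export
enumerate_candidate_triples <- function(observed = NULL,
                                        alphabet = aa_alphabet()) {
  space <- enumerate_triples(alphabet)
  if (is.null(observed) || !length(observed)) return(space)
  obs <- check_triples(observed, alphabet = alphabet)
  keep <- !(triple_strings(space) %in% triple_strings(obs))
  space[keep, , drop = FALSE]
}

#' Stage 1 of the cascade: keep candidates predicted "improved"
#'
#' Applies the improved-vs-non-improved discriminator to every candidate
#' triple and keeps those with predicted probability of improvement above
#' 0.5, preserving enumeration order.
#'
#' @param model `discrimination_model` trained with the improved class
#'   positive.
#' @param candidates Candidate triples.
#' @param table `descriptor_table` used for encoding (must match the
#'   model's training encoding).
#' @return List with `kept` (triple matrix), `p_improved` (probabilities of
#'   the kept triples), and `n_rejected`.
#' @export
screen_stage1 <- function(model, candidates, table) {
  cand <- check_triples(candidates)
  x <- encode_variants(cand, table)
  p <- predict(model, x, type = "prob")
  keep <- p > 0.5
  list(kept = cand[keep, , drop = FALSE],
       p_improved = p[keep],
       n_rejected = sum(!keep))
}

#' Stage 2 of the cascade: rank survivors by high-class probability
#'
#' Applies the high-vs-medium discriminator to the stage-1 survivors and
#' orders them by decreasing probability of high thermostability
#' improvement. Exact probability ties are broken by lexicographic alphabet
#' order of the triple; ranks are consecutive from 1.
#'
#' @param model `discrimination_model` trained with the high class positive.
#' @param candidates Triples that survived stage 1.
#' @param table `descriptor_table` used for encoding.
#' @param p_improved Optional stage-1 probabilities carried through to the
#'   output.
#' @return A `candidate_ranking` data frame: `rank`, `pos1..pos3`, `triple`,
#'   `p_high` (and `p_improved` if supplied).
#' @export
rank_stage2 <- function(model, candidates, table, p_improved = NULL) {
  cand <- check_triples(candidates)
  if (nrow(cand) == 0L) {
    out <- data.frame(rank = integer(), pos1 = character(),
                      pos2 = character(), pos3 = character(),
                      triple = character(), p_high = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_ranking", class(out))
    return(out)
  }
  x <- encode_variants(cand, table)
  p <- predict(model, x, type = "prob")
  # lexicographic tie-break via position in the full enumeration order
  alphabet <- aa_alphabet()
  lex <- (match(cand[, 1L], alphabet) - 1L) * 400L +
         (match(cand[, 2L], alphabet) - 1L) * 20L +
          match(cand[, 3L], alphabet)
  ord <- order(-p, lex, method = "radix")
  out <- data.frame(rank = seq_len(nrow(cand)),
                    pos1 = cand[ord, 1L], pos2 = cand[ord, 2L],
                    pos3 = cand[ord, 3L],
                    triple = triple_strings(cand[ord, , drop = FALSE]),
                    p_high = p[ord], stringsAsFactors = FALSE)
  if (!is.null(p_improved)) out$p_improved <- p_improved[ord]
  class(out) <- c("candidate_ranking", class(out))
  out
}

#' Select promising candidates for experimental validation
#'
#' From a stage-2 ranking, takes the top `n_high` entries as the
#' high-improvement picks and, separately, the best `n_medium` entries among
#' those predicted medium (p_high <= 0.5) and not already selected, again in
#' descending p_high order. The two lists are therefore always disjoint. If
#' a quota cannot be filled, all available entries are returned with a
#' warning.
#'
#' @param ranking A `candidate_ranking`.
#' @param n_high,n_medium Selection sizes.
#' @return List of two `candidate_ranking` subsets, `high` and `medium`.
#' @export
select_top_candidates <- function(ranking, n_high = 20L, n_medium = 20L) {
  high_sel <- utils::head(ranking, n_high)
  if (nrow(high_sel) < n_high) {
    warning(sprintf("only %d ranked candidates available; requested %d high",
                    nrow(high_sel), n_high), call. = FALSE)
  }
  med_pool <- ranking[ranking$p_high <= 0.5 &
                        !(ranking$rank %in% high_sel$rank), , drop = FALSE]
  if (nrow(med_pool) < n_medium) {
    warning(sprintf("only %d candidates predicted medium; requested %d",
                    nrow(med_pool), n_medium), call. = FALSE)
  }
  list(high = high_sel, medium = utils::head(med_pool, n_medium))
}
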