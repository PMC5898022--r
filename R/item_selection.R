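collapse_profile <- function(v, how = "mean") {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(0)
  switch(how, mean = mean(v), sum = sum(v), max = max(v))
}

#' Score one candidate disease from the neighbours' known indications
#'
#' \code{score(c, t) = sum_n sim(t, n) * f(n, c)} where \code{f(n, c)} is
#' the binary neighbour-disease indication from the golden matrix. Under
#' the SUM policy the similarity weight is dropped and the score is a
#' plain vote count; under WSUM \code{sim(t, n)} is the scalar collapse
#' (config \code{collapse}) of the neighbour's per-source profile.
#'
#' @param disease disease name (a golden column).
#' @param neighbors a \code{\link{select_neighbors}} result.
#' @param golden a \code{\link{golden_associations}} matrix; in
#'   leave-one-out runs the target's own row must already be withheld.
#' @param profiles the candidates-x-sources similarity matrix the
#'   neighbours were selected from (needed for WSUM).
#' @param ist item-selection policy, \code{"WSUM"} or \code{"SUM"}.
#' @param collapse profile-to-scalar rule for WSUM.
#' @return non-negative score.
#' @export
score_candidate <- function(disease, neighbors, golden, profiles = NULL,
                            ist = c("WSUM", "SUM"), collapse = "mean") {
  ist <- match.arg(ist)
  nb <- intersect(neighbors$neighbor, rownames(golden))
  if (length(nb) == 0L) return(0)
  f <- as.numeric(golden[nb, disease])
  if (ist == "SUM") return(sum(f))
  stopifnot(!is.null(profiles))
  w <- apply(as.matrix(profiles)[nb, , drop = FALSE], 1L, collapse_profile,
             how = collapse)
  sum(w * f)
}

#' Predict disease indications for a target drug
#'
#' Runs the full pipeline for one target: per-source similarity profiles,
#' Pareto-dominance neighbour selection, and neighbour-vote disease
#' scoring. Only diseases indicated by at least one neighbour can be
#' proposed -- the method never pads the list with guesses -- so the
#' result holds at most \code{k} entries and may hold fewer.
#'
#' @param dataset a \code{\link{repo_dataset}}.
#' @param target drug name.
#' @param config a \code{\link{similarity_config}}.
#' @param mot,n neighbour-selection policy and count, see
#'   \code{\link{select_neighbors}}.
#' @param ist scoring policy, \code{"WSUM"} or \code{"SUM"}.
#' @param k maximum output list length (a cap, not a quota).
#' @param simmats optional precomputed \code{\link{similarity_matrices}}.
#' @param golden_override golden matrix to use for neighbour votes
#'   instead of \code{dataset$golden}; leave-one-out evaluation passes
#'   the matrix with the target row withheld.
#' @return data.frame of class \code{"prediction_list"} with columns
#'   \code{disease}, \code{score}, \code{rank}, ordered by decreasing
#'   score (ties by disease name); attributes \code{target} and
#'   \code{k_limit}. Scores are strictly positive.
#' @export
predict_indications <- function(dataset, target, config = similarity_config(),
                                mot = "ND", n = 4L, ist = "WSUM", k = 4L,
                                simmats = NULL, golden_override = NULL) {
  stopifnot(k >= 1L)
  ist <- match.arg(ist, c("WSUM", "SUM"))
  golden <- golden_override %||% dataset$golden
  profiles <- build_profiles(dataset, target, config, simmats = simmats)
  # the target's own votes must never reach the scoring step
  keep <- setdiff(rownames(golden), target)
  golden <- golden[keep, , drop = FALSE]
  nbrs <- withCallingHandlers(
    select_neighbors(profiles, mot = mot, n = n),
    warning = function(w) invokeRestart("muffleWarning"))
  empty <- data.frame(disease = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (nrow(nbrs) == 0L) {
    warning("target '", target, "' has no neighbors; empty prediction list")
    return(structure(empty, target = target, k_limit = as.integer(k),
                     class = c("prediction_list", "data.frame")))
  }
  nb <- intersect(nbrs$neighbor, rownames(golden))
  votes <- colSums(golden[nb, , drop = FALSE])
  cand <- names(votes)[votes > 0]
  if (length(cand) == 0L)
    return(structure(empty, target = target, k_limit = as.integer(k),
                     class = c("prediction_list", "data.frame")))
  if (ist == "SUM") {
    scores <- votes[cand]
  } else {
    w <- apply(as.matrix(profiles)[nb, , drop = FALSE], 1L, collapse_profile,
               how = config$collapse)
    scores <- colSums(w * golden[nb, cand, drop = FALSE])
  }
  ord <- order(-scores, cand)
  cand <- cand[ord]; scores <- scores[ord]
  pos <- scores > 0
  cand <- cand[pos]; scores <- scores[pos]
  take <- seq_len(min(k, length(cand)))
  structure(data.frame(disease = cand[take], score = unname(scores[take]),
                       rank = take, stringsAsFactors = FALSE),
            target = target, k_limit = as.integer(k),
            class = c("prediction_list", "data.frame"))
}

#' @export
print.prediction_list <- function(x, ...) {
  cat(sprintf("prediction_list for '%s' (k <= %d): %d disease(s)\n",
              attr(x, "target") %||% "?", attr(x, "k_limit") %||% NA, nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
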