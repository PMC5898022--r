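#' Pareto dominance between two similarity profiles
#'
#' Profile \code{p} dominates \code{q} when it is at least as similar to
#' the target on every feature source and strictly more similar on at
#' least one. Undefined (\code{NA}) similarities are read as 0: absence
#' of evidence confers no advantage.
#'
#' @param p,q numeric vectors of per-source similarities to the same
#'   target, in the same source order.
#' @return 1 if \code{p} dominates \code{q}, else 0.
#' @examples
#' dominates(c(0.9, 0.2), c(0.4, 0.1))  # 1
#' dominates(c(0.9, 0.2), c(0.5, 0.5))  # 0 (mutually non-dominating)
#' @export
dominates <- function(p, q) {
  stopifnot(length(p) == length(q))
  p[is.na(p)] <- 0
  q[is.na(q)] <- 0
  as.integer(all(p >= q) && any(p > q))
}

#' Pairwise dominance matrix of a set of candidate profiles
#'
#' @param profiles numeric matrix, candidates x feature sources (rows
#'   named by candidate), as from \code{\link{build_profiles}}.
#' @return binary matrix D with \code{D[i, j] = 1} iff candidate i
#'   dominates candidate j; the diagonal is 0 and D is antisymmetric in
#'   the sense that \code{D[i, j] = 1} implies \code{D[j, i] = 0}.
#' @export
dominance_matrix <- function(profiles) {
  P <- as.matrix(profiles)
  P[is.na(P)] <- 0
  n <- nrow(P)
  D <- matrix(0L, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n)) {
    geq <- colSums(t(P) >= P[i, ]) == ncol(P)   # i >= j everywhere? no: j vs i
    gt  <- colSums(t(P) >  P[i, ]) > 0
    D[, i] <- as.integer(geq & gt)              # column i: who dominates i
  }
  diag(D) <- 0L
  D
}

#' Non-dominated candidates (the first Pareto front)
#'
#' A candidate is selected when no other candidate dominates it, i.e. its
#' column total in the dominance matrix is zero.
#'
#' @inheritParams dominance_matrix
#' @return character vector of non-dominated candidate names, in input
#'   order.
#' @export
non_dominated_set <- function(profiles) {
  if (nrow(profiles) == 0L) return(character())
  D <- dominance_matrix(profiles)
  rownames(D)[colSums(D) == 0L]
}

profile_means <- function(profiles) {
  rowMeans(as.matrix(profiles), na.rm = TRUE)
}

#' Select neighbour drugs by iterated Pareto dominance
#'
#' Successive non-dominated fronts are peeled off the candidate set until
#' the collection policy is satisfied:
#' \describe{
#'   \item{OD (Only-Dominates)}{a single iteration; the neighbour count is
#'     whatever the first front holds.}
#'   \item{ND (N-Dominates)}{iterate until at least \code{n} neighbours
#'     are collected, then prune the final front so exactly \code{n}
#'     remain.}
#'   \item{AND (At-Least-N-Dominates)}{same iteration but no pruning, so
#'     at least \code{n} neighbours are returned unless the candidate
#'     pool is exhausted first.}
#' }
#' Pruning keeps the final-front members with the highest mean defined
#' similarity, ties broken by drug name, so selection is deterministic.
#' Candidates whose profile is entirely undefined or zero are excluded
#' up front: with no evidence of similarity they cannot be neighbours.
#'
#' @param profiles candidates-x-sources similarity matrix from
#'   \code{\link{build_profiles}}.
#' @param mot collection policy, one of \code{"OD"}, \code{"ND"},
#'   \code{"AND"}.
#' @param n requested neighbour count (ignored by OD).
#' @return a data.frame of class \code{"neighbor_set"} with columns
#'   \code{neighbor} and \code{iteration} (the front index each neighbour
#'   came from) and attribute \code{target}.
#' @export
select_neighbors <- function(profiles, mot = c("ND", "OD", "AND"), n = 1L) {
  mot <- match.arg(mot)
  stopifnot(n >= 1L)
  P <- as.matrix(profiles)
  keep <- rowSums(!is.na(P) & P > 0) > 0
  P <- P[keep, , drop = FALSE]
  out <- data.frame(neighbor = character(), iteration = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(P) == 0L) {
    warning("no candidate has any defined nonzero similarity; empty neighbor set")
  } else if (mot == "OD") {
    out <- data.frame(neighbor = non_dominated_set(P), iteration = 1L,
                      stringsAsFactors = FALSE)
  } else {
    if (mot != "OD" && n > nrow(P))
      warning(sprintf("requested %d neighbors but only %d usable candidates", n, nrow(P)))
    iter <- 0L
    max_iter <- nrow(P)
    while (nrow(out) < n && nrow(P) > 0L && iter < max_iter) {
      iter <- iter + 1L
      front <- non_dominated_set(P)
      if (length(front) == 0L) break  # cannot happen on finite profiles
      if (mot == "ND" && nrow(out) + length(front) > n) {
        room <- n - nrow(out)
        means <- profile_means(P[front, , drop = FALSE])
        front <- front[order(-means, front)][seq_len(room)]
      }
      out <- rbind(out, data.frame(neighbor = front, iteration = iter,
                                   stringsAsFactors = FALSE))
      P <- P[setdiff(rownames(P), front), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  structure(out, target = attr(profiles, "target"),
            class = c("neighbor_set", "data.frame"))
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat(sprintf("neighbor_set for target '%s': %d neighbor(s) over %s front(s)\n",
              attr(x, "target") %||% "?", nrow(x),
              if (nrow(x)) max(x$iteration) else 0L))
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Successive Pareto fronts of a candidate set
#'
#' Utility used in testing and inspection: peels non-dominated fronts
#' until the candidate set is exhausted.
#'
#' @inheritParams dominance_matrix
#' @return list of character vectors, one per front.
#' @export
pareto_fronts <- function(profiles) {
  P <- as.matrix(profiles)
  fronts <- list()
  while (nrow(P) > 0L) {
    f <- non_dominated_set(P)
    if (length(f) == 0L) break
    fronts[[length(fronts) + 1L]] <- f
    P <- P[setdiff(rownames(P), f), , drop = FALSE]
  }
  fronts
}
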