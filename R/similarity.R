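#' Similarity configuration
#'
#' Fixes, per data source, which similarity measure is used, plus the
#' local-alignment scoring parameters and how a neighbour's per-feature
#' similarity profile is collapsed to the scalar used by weighted voting.
#'
#' Shorthand codes mirror the usual experiment settings: three letters
#' for the (chemical, side-effect, protein) sources with C = cosine,
#' J = Jaccard/Tanimoto, S = Smith-Waterman alignment. So \code{"CCC"}
#' is cosine everywhere, \code{"JJC"} is Jaccard for chemical and
#' side-effect with cosine for protein, and \code{"JJS"} swaps in the
#' alignment-based protein similarity.
#'
#' @param measures either a shorthand code (\code{"CCC"}, \code{"JJJ"},
#'   \code{"JJC"}, \code{"JJS"}) or a named character vector
#'   source -> measure with measures in \code{c("cosine", "jaccard",
#'   "smith_waterman")}.
#' @param match,mismatch alignment substitution scores (match positive).
#' @param gap linear gap penalty per gapped position, as a (negative)
#'   score contribution.
#' @param normalize if TRUE (default) each pairwise alignment score is
#'   divided by \code{sqrt(SW(x,x) * SW(y,y))} so the sequence-set
#'   similarity lies in [0, 1] and is commensurable with cosine/Jaccard
#'   inside Pareto comparisons; FALSE gives the raw mean alignment score.
#' @param collapse how to collapse a profile to the scalar sim(t, n) used
#'   by weighted voting: \code{"mean"} (default), \code{"sum"} or
#'   \code{"max"} over the defined per-source similarities.
#' @return a list of class \code{"similarity_config"}.
#' @examples
#' similarity_config("JJS")
#' similarity_config(c(chemical = "jaccard", side_effect = "cosine"))
#' @export
similarity_config <- function(measures = "CCC", match = 2, mismatch = -1,
                              gap = -1, normalize = TRUE, collapse = "mean") {
  if (length(measures) == 1L && is.null(names(measures)) &&
      grepl("^[CJS]{3}$", measures)) {
    letters3 <- strsplit(measures, "")[[1L]]
    key <- c(C = "cosine", J = "jaccard", S = "smith_waterman")
    measures <- setNames(key[letters3],
                         c("chemical", "side_effect", "protein"))
  }
  ok <- c("cosine", "jaccard", "smith_waterman")
  if (is.null(names(measures)) || !all(measures %in% ok))
    stop("measures must be a 3-letter shorthand or a named vector over ",
         paste(ok, collapse = "/"), call. = FALSE)
  stopifnot(match > 0, is.numeric(mismatch), is.numeric(gap), gap <= 0)
  collapse <- match.arg(collapse, c("mean", "sum", "max"))
  structure(list(measures = measures, match = match, mismatch = mismatch,
                 gap = gap, normalize = isTRUE(normalize), collapse = collapse),
            class = "similarity_config")
}

#' @export
print.similarity_config <- function(x, ...) {
  cat("similarity_config:",
      paste(names(x$measures), x$measures, sep = "=", collapse = ", "),
      sprintf("| align match=%g mismatch=%g gap=%g, normalize=%s, collapse=%s\n",
              x$match, x$mismatch, x$gap, x$normalize, x$collapse))
  invisible(x)
}

#' Cosine similarity of two binary vectors
#'
#' \code{sum(a*b) / (||a|| * ||b||)}. A zero vector yields similarity 0
#' rather than an error, so fully sparse drugs degrade gracefully.
#'
#' @param a,b equal-length binary vectors.
#' @return similarity in [0, 1].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Jaccard (Tanimoto) similarity of two binary vectors
#'
#' \code{|AB| / (|A| + |B| - |AB|)} with |AB| the count of shared ones.
#' Two all-zero vectors yield 0.
#'
#' @inheritParams cosine_similarity
#' @return similarity in [0, 1].
#' @export
jaccard_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a * b)
  union <- sum(a) + sum(b) - inter
  if (union == 0) return(0)
  inter / union
}

align_substitution_matrix <- function(match, mismatch, alphabet = AA_ALPHABET) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two residue strings under a simple
#' match/mismatch substitution scheme and a linear gap penalty. The empty
#' alignment scores 0, so the result is never negative.
#'
#' @param x,y non-empty residue strings over \code{alphabet}.
#' @param match,mismatch,gap scoring parameters (gap is the per-position
#'   penalty, a non-positive number).
#' @param alphabet allowed residues.
#' @return non-negative alignment score.
#' @examples
#' smith_waterman_score("ACDE", "ACDE")  # 4 matches * 2 = 8
#' smith_waterman_score("AAAA", "CCCC")  # no positive local alignment: 0
#' @export
smith_waterman_score <- function(x, y, match = 2, mismatch = -1, gap = -1,
                                 alphabet = AA_ALPHABET) {
  stopifnot(nzchar(x), nzchar(y))
  check_alphabet(x, alphabet)
  check_alphabet(y, alphabet)
  sub <- align_substitution_matrix(match, mismatch, alphabet)
  s <- Biostrings::pairwiseAlignment(x, y, type = "local",
                                     substitutionMatrix = sub,
                                     gapOpening = 0, gapExtension = abs(gap),
                                     scoreOnly = TRUE)
  max(0, s)
}

# All-pairs local-alignment scores for a character vector of sequences,
# computed column-wise (one vectorized alignment call per subject).
sw_score_matrix <- function(seqs, match, mismatch, gap, alphabet = AA_ALPHABET,
                            normalize = FALSE) {
  sub <- align_substitution_matrix(match, mismatch, alphabet)
  pats <- Biostrings::AAStringSet(seqs)
  n <- length(seqs)
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    S[, j] <- pmax(0, Biostrings::pairwiseAlignment(
      pats, seqs[[j]], type = "local", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = abs(gap), scoreOnly = TRUE))
  }
  if (normalize) {
    self <- diag(S)
    S <- S / sqrt(outer(self, self))
  }
  S
}

#' Similarity of two sets of sequences
#'
#' Mean pairwise local-alignment score over all cross pairs of the two
#' sequence sets: \code{sum_ij SW(va_i, vb_j) / (|va| * |vb|)}. With
#' \code{normalize = TRUE} each pairwise score is first divided by
#' \code{sqrt(SW(x,x) * SW(y,y))}, bounding the result by 1.
#'
#' @param va,vb non-empty character vectors of residue strings.
#' @inheritParams smith_waterman_score
#' @param normalize normalize each pairwise score by the self-alignment
#'   geometric mean.
#' @return non-negative similarity (in [0, 1] when normalized).
#' @export
sequence_set_similarity <- function(va, vb, match = 2, mismatch = -1, gap = -1,
                                    normalize = TRUE, alphabet = AA_ALPHABET) {
  if (length(va) == 0L || length(vb) == 0L)
    stop("sequence sets must be non-empty", call. = FALSE)
  S <- sw_score_matrix(c(va, vb), match, mismatch, gap, alphabet,
                       normalize = normalize)
  mean(S[seq_along(va), length(va) + seq_along(vb), drop = FALSE])
}

# Full symmetric similarity matrix for one binary feature source; rows of
# X are drugs. Zero rows get similarity 0 to everything (including
# themselves, by the both-empty convention for jaccard; cosine likewise).
binary_similarity_matrix <- function(X, measure) {
  X <- unclass(X)
  storage.mode(X) <- "double"
  inter <- tcrossprod(X)
  r <- rowSums(X)
  if (measure == "cosine") {
    denom <- outer(sqrt(r), sqrt(r))
  } else {
    denom <- outer(r, r, "+") - inter
  }
  sim <- ifelse(denom > 0, inter / denom, 0)
  dimnames(sim) <- list(rownames(X), rownames(X))
  sim
}

# Drug x drug similarity per drug from the sequence map.
sequence_similarity_matrix <- function(sequences, config) {
  drugs <- names(sequences)
  lens <- lengths(sequences)
  drugs <- drugs[lens > 0L]
  allseq <- unlist(sequences[drugs], use.names = FALSE)
  grp <- rep(seq_along(drugs), lengths(sequences[drugs]))
  alpha <- attr(sequences, "alphabet")
  if (is.null(alpha)) alpha <- AA_ALPHABET
  S <- sw_score_matrix(allseq, config$match, config$mismatch, config$gap,
                       alphabet = alpha, normalize = config$normalize)
  # mean over all cross pairs of the two drugs' sequence sets
  G <- rowsum(t(rowsum(S, grp)), grp)  # sums per drug pair
  cnt <- outer(lengths(sequences[drugs]), lengths(sequences[drugs]))
  sim <- t(G) / cnt
  dimnames(sim) <- list(drugs, drugs)
  sim
}

#' Precompute all drug-by-drug similarity matrices of a dataset
#'
#' For each feature source named in the configuration, computes the full
#' pairwise similarity among the golden drugs under the configured
#' measure. Drugs absent from a source (no feature row; for the
#' alignment measure, no sequences) get \code{NA} against everyone in
#' that source -- downstream dominance reads \code{NA} as 0.
#'
#' @param dataset a \code{\link{repo_dataset}}.
#' @param config a \code{\link{similarity_config}}.
#' @return named list of symmetric numeric matrices (golden drugs x
#'   golden drugs), one per configured source present in the dataset.
#' @export
similarity_matrices <- function(dataset, config = similarity_config()) {
  drugs <- rownames(dataset$golden)
  sources <- intersect(names(config$measures),
                       union(names(dataset$features),
                             if (!is.null(dataset$sequences)) "protein"))
  out <- list()
  for (src in sources) {
    measure <- config$measures[[src]]
    full <- matrix(NA_real_, length(drugs), length(drugs),
                   dimnames = list(drugs, drugs))
    if (measure == "smith_waterman") {
      if (is.null(dataset$sequences))
        stop("measure 'smith_waterman' for source '", src,
             "' requires per-drug sequences", call. = FALSE)
      sim <- sequence_similarity_matrix(dataset$sequences, config)
    } else {
      if (is.null(dataset$features[[src]])) next
      sim <- binary_similarity_matrix(dataset$features[[src]], measure)
    }
    present <- intersect(drugs, rownames(sim))
    full[present, present] <- sim[present, present]
    out[[src]] <- full
  }
  if (length(out) == 0L)
    stop("no configured source matches the dataset", call. = FALSE)
  out
}

#' Per-candidate similarity profiles for one target drug
#'
#' One row per candidate drug (every golden drug except the target), one
#' column per feature source; \code{NA} marks an undefined similarity
#' (either drug absent from that source).
#'
#' @param dataset a \code{\link{repo_dataset}}.
#' @param target a drug name present in at least one feature source.
#' @param config a \code{\link{similarity_config}}.
#' @param simmats optional precomputed \code{\link{similarity_matrices}}
#'   result, to avoid recomputation in repeated calls.
#' @return numeric matrix (candidates x sources) of class
#'   \code{"similarity_profiles"} with a \code{target} attribute.
#' @export
build_profiles <- function(dataset, target, config = similarity_config(),
                           simmats = NULL) {
  if (!target %in% feature_drugs(dataset) &&
      !(!is.null(dataset$sequences) && target %in% names(dataset$sequences)))
    stop("target drug '", target, "' is unknown to every feature source",
         call. = FALSE)
  if (is.null(simmats)) simmats <- similarity_matrices(dataset, config)
  drugs <- rownames(dataset$golden)
  cands <- setdiff(drugs, target)
  prof <- vapply(simmats, function(m) {
    if (target %in% rownames(m)) m[cands, target] else rep(NA_real_, length(cands))
  }, numeric(length(cands)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = length(cands))
  dimnames(prof) <- list(cands, names(simmats))
  structure(prof, target = target, class = c("similarity_profiles", "matrix"))
}
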