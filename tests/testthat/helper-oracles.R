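# Independent oracle implementations used to cross-check the package.
# Each deliberately takes a different algorithmic route than the code
# under test.

# Local alignment score as the maximum, over every pair of substrings,
# of a global Needleman-Wunsch alignment of the two substrings. The
# empty substring pair contributes 0.
oracle_global_align <- function(a, b, match, mismatch, gap) {
  m <- length(a); n <- length(b)
  G <- matrix(0, m + 1L, n + 1L)
  G[, 1L] <- gap * (0:m)
  G[1L, ] <- gap * (0:n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- if (a[i] == b[j]) match else mismatch
    G[i + 1L, j + 1L] <- max(G[i, j] + s, G[i, j + 1L] + gap,
                             G[i + 1L, j] + gap)
  }
  G[m + 1L, n + 1L]
}

oracle_local_align <- function(x, y, match = 2, mismatch = -1, gap = -1) {
  a <- strsplit(x, "")[[1L]]
  b <- strsplit(y, "")[[1L]]
  best <- 0
  for (i1 in seq_along(a)) for (i2 in i1:length(a))
    for (j1 in seq_along(b)) for (j2 in j1:length(b))
      best <- max(best, oracle_global_align(a[i1:i2], b[j1:j2],
                                            match, mismatch, gap))
  best
}

# Quadratic all-pairs dominance check; NA similarities read as 0.
oracle_non_dominated <- function(P) {
  P <- as.matrix(P)
  P[is.na(P)] <- 0
  n <- nrow(P)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && all(P[j, ] >= P[i, ]) && any(P[j, ] > P[i, ]))
      keep[i] <- FALSE
  }
  rownames(P)[keep]
}

# AUC-ROC by explicit positive/negative pair counting, ties worth 1/2.
oracle_auc_roc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# AUC-PR by explicit threshold sweep over the distinct score values,
# trapezoid between consecutive (recall, precision) points, anchored at
# recall 0 with the first achievable precision.
oracle_auc_pr <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(th, function(s) {
    sel <- scores >= s
    c(rec = sum(labels[sel] == 1) / P,
      prec = sum(labels[sel] == 1) / sum(sel))
  }, c(rec = 0, prec = 0)))
  rec <- c(0, pts[, "rec"]); prec <- c(pts[1L, "prec"], pts[, "prec"])
  sum(diff(rec) * (prec[-length(prec)] + prec[-1L]) / 2)
}

random_profile_matrix <- function(n_cand, n_feat = 3L, na_frac = 0) {
  P <- matrix(round(runif(n_cand * n_feat), 2), n_cand, n_feat,
              dimnames = list(sprintf("c%02d", seq_len(n_cand)),
                              paste0("f", seq_len(n_feat))))
  if (na_frac > 0) P[runif(length(P)) < na_frac] <- NA
  P
}

# Three explicit Pareto fronts of two mutually non-dominating profiles
# each; front i+1 is strictly below front i in both coordinates.
three_front_profiles <- function() {
  P <- rbind(a1 = c(1.0, 0.9), a2 = c(0.9, 1.0),
             b1 = c(0.8, 0.7), b2 = c(0.7, 0.8),
             c1 = c(0.6, 0.5), c2 = c(0.5, 0.6))
  colnames(P) <- c("f1", "f2")
  structure(P, target = "t", class = c("similarity_profiles", "matrix"))
}

# Tiny fully-specified dataset: two 2-drug clusters with disjoint
# features and indications, plus per-drug sequences.
toy_dataset <- function() {
  chem <- feature_matrix(rbind(
    d1 = c(1, 1, 0, 0), d2 = c(1, 1, 0, 0),
    d3 = c(0, 0, 1, 1), d4 = c(0, 0, 1, 1)),
    source_name = "chemical",
    feature_ids = paste0("s", 1:4))
  se <- feature_matrix(rbind(
    d1 = c(1, 0), d2 = c(1, 0), d3 = c(0, 1), d4 = c(0, 1)),
    source_name = "side_effect", feature_ids = c("e1", "e2"))
  golden <- golden_associations(rbind(
    d1 = c(1, 1, 0, 0), d2 = c(1, 1, 0, 0),
    d3 = c(0, 0, 1, 1), d4 = c(0, 0, 1, 1)),
    disease_ids = paste0("dis", 1:4))
  seqs <- sequence_features(list(
    d1 = "ACDEFGHIKL", d2 = "ACDEFGHIKL",
    d3 = "YWVTSRQPNM", d4 = "YWVTSRQPNM"))
  repo_dataset(list(chemical = chem, side_effect = se), golden, seqs)
}
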