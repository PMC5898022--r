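#' Confusion counts for one target at list size k
#'
#' @param tp,fp,fn,tn non-negative integer counts (predicted-and-true,
#'   predicted-but-false, missed-true, correctly-unpredicted).
#' @param k the output list-size cap; \code{tp + fp <= k}.
#' @return list of class \code{"confusion_counts"}.
#' @export
confusion_counts <- function(tp, fp, fn, tn, k = tp + fp) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp <= k)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, k = k),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' \code{precision = tp/(tp+fp)}, \code{recall = tp/(tp+fn)},
#' \code{F1 = 2PR/(P+R)}. A zero denominator yields 0 (an empty
#' prediction list counts as precision 0, penalising abstention in
#' averages rather than skipping it).
#'
#' @param counts a \code{\link{confusion_counts}} object (or any list
#'   with tp/fp/fn fields).
#' @return named numeric vector \code{c(precision, recall, f1)}.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Specificity (true-negative rate) from confusion counts
#'
#' \code{tn / (tn + fp)}: performance on negative (non-indicated)
#' drug-disease links.
#'
#' @inheritParams precision_recall_f1
#' @return value in [0, 1].
#' @export
specificity <- function(counts) {
  tn <- counts$tn; fp <- counts$fp
  if (tn + fp == 0) stop("specificity undefined: tn + fp = 0", call. = FALSE)
  tn / (tn + fp)
}

#' Area under the precision-recall curve
#'
#' Traverses the ranking from the highest score down, grouping tied
#' scores, and integrates precision over recall by the trapezoid rule
#' across the achievable curve points, anchored at recall 0 with the
#' first point's precision. With all scores tied this reduces to the
#' positive prevalence.
#'
#' @param scores numeric prediction scores, higher = more confident.
#' @param labels binary ground truth, same length.
#' @return area in [0, 1].
#' @export
auc_pr <- function(scores, labels) {
  y <- check_ranking(scores, labels)
  P <- sum(y)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))
  ctp <- cumsum(vapply(split(y, grp), sum, 0))
  cn <- cumsum(vapply(split(y, grp), length, 0))
  prec <- ctp / cn
  rec <- ctp / P
  rec <- c(0, rec); prec <- c(prec[1L], prec)
  sum(diff(rec) * (prec[-length(prec)] + prec[-1L]) / 2)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outranks a random negative, ties counted half.
#'
#' @inheritParams auc_pr
#' @return area in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  y <- check_ranking(scores, labels)
  P <- sum(y); N <- length(y) - P
  r <- rank(scores)
  (sum(r[y == 1]) - P * (P + 1) / 2) / (P * N)
}

check_ranking <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels != 0)
  if (sum(y) == 0L || sum(y) == length(y))
    stop("need at least one positive and one negative label", call. = FALSE)
  y
}

#' Analytic upper bounds of precision/recall/F1 at list size k
#'
#' For a target with p known indications and list size k, no method can
#' do better than tp = min(p, k). With forced guessing (the list is
#' padded to exactly k entries) the remaining fp = k - tp slots are
#' wrong whenever p < k; without guessing (at most k entries) fp = 0 and
#' precision is always exactly 1. Per-target metrics are averaged over
#' all golden drugs with at least one indication.
#'
#' @param golden a \code{\link{golden_associations}} matrix.
#' @param k_values integer vector of list sizes.
#' @param allow_guess TRUE for the padded-to-k bound, FALSE for the
#'   at-most-k bound.
#' @return data.frame with columns k, precision, recall, f1.
#' @export
upper_bounds <- function(golden, k_values = c(1, 4, 8, 12, 16, 20),
                         allow_guess = FALSE) {
  p <- rowSums(golden)
  p <- p[p > 0]
  out <- lapply(k_values, function(k) {
    tp <- pmin(p, k)
    fp <- if (allow_guess) k - tp else 0
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    rec <- tp / p
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    data.frame(k = k, precision = mean(prec), recall = mean(rec),
               f1 = mean(f1))
  })
  do.call(rbind, out)
}

#' Leave-one-out evaluation of the repositioning pipeline
#'
#' For every target drug with at least one known indication, the target's
#' golden row is withheld, the pipeline predicts up to \code{k} diseases
#' from the remaining drugs' indications, and the prediction is scored
#' against the withheld row. The true-negative universe per target is
#' that drug's full disease row, so tn = diseases - tp - fp - fn.
#' AUC-PR and AUC-ROC rank the target's whole disease row by prediction
#' score (unpredicted diseases score 0) and are computed per target then
#' averaged; \code{auc_pooling = "pooled"} instead pools all
#' (drug, disease) pairs into one ranking.
#'
#' @param dataset a \code{\link{repo_dataset}}.
#' @param config a \code{\link{similarity_config}}.
#' @param mot,n,ist,k pipeline settings, see
#'   \code{\link{predict_indications}}.
#' @param targets drug names to evaluate; default all golden drugs with
#'   at least one positive. Targets with no positives are skipped with a
#'   warning.
#' @param auc_pooling \code{"per_target"} (default) or \code{"pooled"}.
#' @param simmats optional precomputed \code{\link{similarity_matrices}}.
#' @return list of class \code{"evaluation_report"}: \code{$per_target}
#'   data.frame, \code{$summary} named means over targets, and the
#'   settings used.
#' @export
leave_one_out <- function(dataset, config = similarity_config(), mot = "ND",
                          n = 4L, ist = "WSUM", k = 4L, targets = NULL,
                          auc_pooling = c("per_target", "pooled"),
                          simmats = NULL) {
  auc_pooling <- match.arg(auc_pooling)
  golden <- dataset$golden
  pos_per_drug <- rowSums(golden)
  if (is.null(targets)) {
    targets <- rownames(golden)[pos_per_drug > 0]
  } else {
    zero <- targets[pos_per_drug[targets] == 0]
    if (length(zero)) {
      warning("skipping target(s) with no known indication: ",
              paste(zero, collapse = ", "))
      targets <- setdiff(targets, zero)
    }
  }
  if (is.null(simmats)) simmats <- similarity_matrices(dataset, config)
  diseases <- colnames(golden)
  nd <- length(diseases)
  pooled_scores <- numeric(); pooled_labels <- integer()
  rows <- lapply(targets, function(t) {
    pred <- withCallingHandlers(
      predict_indications(dataset, t, config, mot = mot, n = n, ist = ist,
                          k = k, simmats = simmats),
      warning = function(w) invokeRestart("muffleWarning"))
    truth <- diseases[golden[t, ] == 1]
    tp <- sum(pred$disease %in% truth)
    fp <- nrow(pred) - tp
    fn <- length(truth) - tp
    tn <- nd - tp - fp - fn
    cc <- confusion_counts(tp, fp, fn, tn, k = k)
    prf <- precision_recall_f1(cc)
    svec <- setNames(numeric(nd), diseases)
    svec[pred$disease] <- pred$score
    lvec <- as.integer(golden[t, ] == 1)
    if (auc_pooling == "pooled") {
      pooled_scores <<- c(pooled_scores, svec)
      pooled_labels <<- c(pooled_labels, lvec)
      apr <- NA_real_; aro <- NA_real_
    } else {
      apr <- auc_pr(svec, lvec)
      aro <- auc_roc(svec, lvec)
    }
    data.frame(target = t, tp = tp, fp = fp, fn = fn, tn = tn,
               n_pred = nrow(pred), precision = prf[["precision"]],
               recall = prf[["recall"]], f1 = prf[["f1"]],
               specificity = specificity(cc), auc_pr = apr, auc_roc = aro,
               stringsAsFactors = FALSE)
  })
  per_target <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "f1", "specificity",
                   "auc_pr", "auc_roc")
  summ <- colMeans(per_target[, metric_cols, drop = FALSE])
  if (auc_pooling == "pooled") {
    summ[["auc_pr"]] <- auc_pr(pooled_scores, pooled_labels)
    summ[["auc_roc"]] <- auc_roc(pooled_scores, pooled_labels)
  }
  structure(list(per_target = per_target, summary = summ,
                 settings = list(measures = config$measures, mot = mot,
                                 n = n, ist = ist, k = k,
                                 auc_pooling = auc_pooling,
                                 n_targets = length(targets))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("leave-one-out over %d targets (mot=%s, n=%d, ist=%s, k=%d)\n",
              s$n_targets, s$mot, s$n, s$ist, s$k))
  print(round(x$summary, 4))
  invisible(x)
}
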