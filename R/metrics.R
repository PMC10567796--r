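#' Binary classification metrics
#'
#' Computes accuracy, F1 score, Matthews correlation coefficient (from the
#' confusion table at the argmax threshold), and the areas under the ROC and
#' precision-recall curves by trapezoidal integration over score thresholds.
#'
#' With a single-class label vector the rank-based metrics are undefined:
#' `auroc`/`auprc` are `NA` and `mcc` is reported as 0 with a warning.
#'
#' @param scores Either an N x 2 logit/score matrix (column 2 is the
#'   positive class) or a numeric vector of positive-class scores.
#' @param labels Integer labels in \{0, 1\}.
#' @return An `eval_report`: list with `accuracy`, `f1`, `auroc`, `auprc`,
#'   `mcc` and the 2 x 2 `confusion` table (rows = truth, cols = predicted).
#' @examples
#' evaluate_scores(c(.9, .8, .3, .1), c(1, 1, 0, 0))
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (is.matrix(scores)) {
    stopifnot(ncol(scores) == 2L, nrow(scores) == length(labels))
    pred <- max.col(scores, ties.method = "first") - 1L
    s <- scores[, 2] - scores[, 1]
  } else {
    stopifnot(length(scores) == length(labels))
    s <- as.numeric(scores)
    pred <- as.integer(s > 0)
  }
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  single_class <- length(unique(labels)) < 2L
  if (single_class) {
    warning("labels contain a single class: auROC/auPRC undefined, MCC set to 0")
    mcc <- 0
    auroc <- auprc <- NA_real_
  } else {
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    auroc <- auc_roc(s, labels)
    auprc <- auc_pr(s, labels)
  }
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
                      dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  structure(list(accuracy = acc, f1 = f1, auroc = auroc, auprc = auprc,
                 mcc = mcc, confusion = confusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> accuracy %.4f | F1 %.4f | auROC %s | auPRC %s | MCC %.4f\n",
    x$accuracy, x$f1,
    ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc)),
    ifelse(is.na(x$auprc), "NA", sprintf("%.4f", x$auprc)), x$mcc))
  if (!is.null(x$per_fold)) {
    cat(sprintf("  %d folds; accuracy %.4f +/- %.4f\n", length(x$per_fold),
                x$accuracy, stats::sd(vapply(x$per_fold, `[[`, 0, "accuracy"))))
  }
  invisible(x)
}

# ROC curve by sweeping thresholds over the sorted scores; ties handled by
# grouping equal scores, area by trapezoids
auc_roc <- function(s, labels) {
  ord <- order(s, decreasing = TRUE)
  y <- labels[ord]; sv <- s[ord]
  grp_last <- c(sv[-1] != sv[-length(sv)], TRUE)
  tp <- cumsum(y)[grp_last]; fp <- cumsum(1 - y)[grp_last]
  tpr <- c(0, tp / sum(labels == 1))
  fpr <- c(0, fp / sum(labels == 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# precision-recall area; precision at recall 0 taken as the first observed
# precision, trapezoidal in recall
auc_pr <- function(s, labels) {
  ord <- order(s, decreasing = TRUE)
  y <- labels[ord]; sv <- s[ord]
  grp_last <- c(sv[-1] != sv[-length(sv)], TRUE)
  tp <- cumsum(y)[grp_last]
  n_pred <- which(grp_last)
  prec <- tp / n_pred
  rec <- tp / sum(labels == 1)
  prec <- c(prec[1], prec); rec <- c(0, rec)
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `folds` class-stratified parts (deterministic given
#' `seed`, so different configurations can reuse identical splits), trains
#' one model per fold on the remaining parts and evaluates on the held-out
#' part.
#'
#' @param config A [pam_config()].
#' @param data List of `encoded_seq`.
#' @param labels Integer labels; taken from the sequences when `NULL`.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param verbose Forwarded to [train_model()].
#' @return An `eval_report` whose metrics are means over folds, with
#'   `per_fold` (list of per-fold reports), `sd` (per-metric standard
#'   deviations) and `fold_assignment` attached.
#' @export
cross_validate <- function(config, data, labels = NULL, folds = 5L,
                           seed = 1L, verbose = FALSE) {
  if (is.null(labels)) labels <- sequence_labels(data)
  labels <- as.integer(labels)
  fold_of <- stratified_folds(labels, folds, seed)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    model <- build_model(config, data[tr])
    model <- train_model(model, data[tr], labels[tr], verbose = verbose)
    pr <- predict(model, data[te])
    reports[[f]] <- evaluate_scores(pr$scores, labels[te])
  }
  metrics <- c("accuracy", "f1", "auroc", "auprc", "mcc")
  agg <- lapply(metrics, function(m)
    mean(vapply(reports, `[[`, 0, m)))
  names(agg) <- metrics
  sds <- vapply(metrics, function(m)
    stats::sd(vapply(reports, `[[`, 0, m)), 0)
  confusion <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  out <- c(agg, list(confusion = confusion, per_fold = reports, sd = sds,
                     fold_assignment = fold_of))
  structure(out, class = "eval_report")
}

#' Deterministic stratified fold assignment
#'
#' @param labels Integer class labels.
#' @param folds Number of folds.
#' @param seed RNG seed.
#' @return Integer vector assigning each sample to a fold in `1..folds`.
#' @export
stratified_folds <- function(labels, folds, seed = 1L) {
  stopifnot(folds >= 2)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("every class needs at least `folds` members (smallest has ",
         min(counts), ")")
  }
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == as.integer(cl)))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}
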