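#' Confusion matrix and accuracies
#'
#' Cross-tabulates true by predicted class and reports per-class accuracy
#' (diagonal over row total) and overall accuracy (trace over total), as
#' percentages.
#'
#' @param truth,predicted equal-length label vectors with values in
#'   \code{levels}.
#' @param levels the admissible class labels (default 1:3).
#' @return list with \code{confusion} (true class in rows), \code{per_class}
#'   (percent) and \code{overall} (percent).
#' @export
confusion_and_accuracy <- function(truth, predicted, levels = 1:3) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  if (!all(truth %in% levels) || !all(predicted %in% levels))
    stop("labels outside the admissible classes")
  tf <- factor(truth, levels = levels)
  pf <- factor(predicted, levels = levels)
  cm <- table(truth = tf, predicted = pf)
  per_class <- 100 * diag(cm) / pmax(rowSums(cm), 1)
  overall <- 100 * sum(diag(cm)) / length(truth)
  list(confusion = unclass(cm), per_class = as.numeric(per_class),
       overall = overall)
}

# Pearson chi-square statistic on a 2x2 table, no continuity correction:
# chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
pearson_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

#' Compare two classifiers on a shared prediction set
#'
#' Builds the 2 x 2 table of correct/incorrect counts for the two models and
#' tests whether their accuracies differ. When every expected cell count is
#' at least 5 an uncorrected Pearson chi-square test (1 df) is used;
#' otherwise a two-sided Fisher exact test. p-values are reported unrounded;
#' the conventional display rounds to three decimals.
#'
#' @param correct_a,correct_b number of correctly classified samples for
#'   models A and B.
#' @param n size of the shared prediction set.
#' @param names optional character vector of the two model names.
#' @return list with the contingency \code{table}, \code{test}
#'   (\code{"pearson"} or \code{"fisher"}), \code{statistic} (chi-square, NA
#'   for Fisher) and \code{p_value}.
#' @export
compare_classifiers <- function(correct_a, correct_b, n, names = c("A", "B")) {
  if (n < 1) stop("prediction-set size must be positive")
  if (correct_a < 0 || correct_a > n || correct_b < 0 || correct_b > n)
    stop("correct counts must lie in 0..n")
  tab <- rbind(c(correct_a, n - correct_a),
               c(correct_b, n - correct_b))
  dimnames(tab) <- list(model = names, outcome = c("correct", "incorrect"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    stat <- pearson_chi2_2x2(tab)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(table = tab, test = "pearson", statistic = stat, p_value = p)
  } else {
    p <- stats::fisher.test(tab)$p.value
    list(table = tab, test = "fisher", statistic = NA_real_, p_value = p)
  }
}

#' Evaluate a set of trained classifiers on a shared split
#'
#' Produces, for each model, calibration- and prediction-set confusion
#' matrices with per-class and overall accuracies, plus all pairwise
#' accuracy comparisons on the shared prediction set.
#'
#' @param models named list of \code{trained_classifier} objects.
#' @param Xcal,ycal calibration spectra and labels.
#' @param Xpred,ypred prediction spectra and labels.
#' @param levels admissible class labels.
#' @return object of class \code{"evaluation_report"}: per-model accuracy
#'   tables and a data.frame of pairwise comparisons.
#' @export
evaluate_models <- function(models, Xcal, ycal, Xpred, ypred, levels = 1:3) {
  stopifnot(is.list(models), length(models) >= 1, !is.null(names(models)))
  per_model <- lapply(models, function(m) {
    cal_pred <- predict_class(m, Xcal)
    prd_pred <- predict_class(m, Xpred)
    list(
      calibration = confusion_and_accuracy(ycal, cal_pred, levels),
      prediction = confusion_and_accuracy(ypred, prd_pred, levels),
      n_correct_pred = sum(prd_pred == ypred)
    )
  })
  nm <- names(models)
  pairs <- utils::combn(nm, 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cmp <- compare_classifiers(per_model[[a]]$n_correct_pred,
                               per_model[[b]]$n_correct_pred,
                               length(ypred), names = c(a, b))
    data.frame(model_a = a, model_b = b, test = cmp$test,
               p_value = cmp$p_value)
  }))
  structure(list(models = per_model, comparisons = comparisons,
                 n_prediction = length(ypred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("%s: calibration %.1f%%, prediction %.1f%% (per-class %s)\n",
                nm, m$calibration$overall, m$prediction$overall,
                paste(sprintf("%.1f", m$prediction$per_class), collapse = "/")))
  }
  cat("pairwise prediction-set comparisons:\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %s vs %s: %s p = %.3f\n", cmp$model_a[i], cmp$model_b[i],
                cmp$test[i], cmp$p_value[i]))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits a machine-readable JSON report (confusions, accuracies, pairwise
#' p-values, run metadata) and a delimited accuracy table.
#'
#' @param report an \code{evaluation_report}.
#' @param dir output directory (created if missing).
#' @param manifest optional named list of run metadata (seeds, configs,
#'   selected hyperparameters) echoed into the JSON.
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir, manifest = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    models = lapply(report$models, function(m) list(
      calibration = list(confusion = m$calibration$confusion,
                         per_class = m$calibration$per_class,
                         overall = m$calibration$overall),
      prediction = list(confusion = m$prediction$confusion,
                        per_class = m$prediction$per_class,
                        overall = m$prediction$overall)
    )),
    comparisons = report$comparisons,
    n_prediction = report$n_prediction,
    manifest = manifest
  )
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  acc <- do.call(rbind, lapply(names(report$models), function(nm) {
    m <- report$models[[nm]]
    data.frame(model = nm,
               calibration_overall = round(m$calibration$overall, 1),
               prediction_overall = round(m$prediction$overall, 1))
  }))
  utils::write.table(acc, file.path(dir, "accuracy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    transform(report$comparisons, p_value = round(p_value, 3)),
    file.path(dir, "comparisons.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
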