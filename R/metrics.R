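#' Confusion counts at a decision threshold
#'
#' A node is predicted positive when its probability is greater than or
#' equal to the threshold (the boundary case counts as positive; the rule
#' must be fixed one way for reproducibility).
#'
#' @param prob_pos predicted positive-class probabilities.
#' @param labels true 0/1 labels.
#' @param threshold decision threshold in (0, 1).
#' @return Named integer vector `c(TP, FP, TN, FN)`; the four counts
#'   partition the nodes.
#' @export
confusion_counts <- function(prob_pos, labels, threshold = 0.5) {
  assert_that(length(prob_pos) == length(labels),
              "probabilities and labels differ in length",
              "bindgraph_shape_error")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be 0 or 1",
              "bindgraph_label_error")
  pred <- as.integer(prob_pos >= threshold)
  c(TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L))
}

#' Confusion-matrix metrics for imbalanced binary classification
#'
#' Computes specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2*Pre*Rec/(Pre+Rec)` and the Matthews correlation
#' coefficient
#' `(TP*TN - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A ratio with a zero denominator is reported as 0 and recorded in the
#' `undefined` flag field, so that dataset-level tables stay finite.
#'
#' @param TP,FP,TN,FN non-negative integer counts, not all zero.
#' @return A `metrics_report` list with the four counts, `Spe`, `Pre`,
#'   `Rec`, `F1`, `MCC`, a (initially `NA`) `AUC` slot, and the names of
#'   any metrics whose denominator was zero.
#' @export
compute_metrics <- function(TP, FP, TN, FN) {
  # double arithmetic throughout: products like TP*TN overflow 32-bit ints
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  assert_that(sum(counts) > 0, "all four counts are zero")
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  Spe <- safe_div(TN, TN + FP, "Spe")
  Pre <- safe_div(TP, TP + FP, "Pre")
  Rec <- safe_div(TP, TP + FN, "Rec")
  F1 <- safe_div(2 * Pre * Rec, Pre + Rec, "F1")
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  MCC <- safe_div(TP * TN - FN * FP, mcc_den, "MCC")
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN),
                 Spe = Spe, Pre = Pre, Rec = Rec, F1 = F1, MCC = MCC,
                 AUC = NA_real_, threshold = NA_real_,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP,
              x$TN, x$FN))
  cat(sprintf("  Spe=%.3f Pre=%.3f Rec=%.3f F1=%.3f MCC=%.3f AUC=%s\n",
              x$Spe, x$Pre, x$Rec, x$F1, x$MCC,
              if (is.na(x$AUC)) "NA" else sprintf("%.3f", x$AUC)))
  if (length(x$undefined) > 0L)
    cat(sprintf("  (zero-denominator, reported as 0: %s)\n",
                paste(x$undefined, collapse = ", ")))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, ties counted half — the normalised Mann-Whitney U,
#' equal to the area under the ROC curve.
#'
#' @param prob_pos scores (higher = more positive).
#' @param labels true 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(prob_pos, labels) {
  assert_that(length(prob_pos) == length(labels),
              "scores and labels differ in length", "bindgraph_shape_error")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be 0 or 1",
              "bindgraph_label_error")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present for AUC")
  r <- rank(prob_pos)  # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class-balance summary of labelled datasets
#'
#' Produces the standard dataset-statistics table for binding-residue
#' benchmarks: binding count, non-binding count and the percentage of
#' binding residues, `100 * binding / (binding + non_binding)`, rounded to
#' two decimals.
#'
#' @param x one of: a data frame with columns `dataset`, `binding`,
#'   `non_binding`; a named list of label vectors; a named list of
#'   [protein_graph()]s; or a named character vector of label-file paths.
#' @return Data frame with columns `dataset`, `binding`, `non_binding`,
#'   `pct_binding`.
#' @export
dataset_stats <- function(x) {
  if (is.data.frame(x)) {
    assert_that(all(c("dataset", "binding", "non_binding") %in% names(x)),
                "data frame must have columns dataset, binding, non_binding")
    tab <- x[, c("dataset", "binding", "non_binding")]
  } else {
    assert_that(!is.null(names(x)), "datasets must be named")
    get_labels <- function(el) {
      if (inherits(el, "protein_graph")) el$labels
      else if (is.character(el) && length(el) == 1L) read_labels(el)
      else as.integer(el)
    }
    tab <- do.call(rbind, lapply(names(x), function(nm) {
      lab <- get_labels(x[[nm]])
      data.frame(dataset = nm, binding = sum(lab == 1L),
                 non_binding = sum(lab == 0L))
    }))
  }
  tab$pct_binding <- round(100 * tab$binding / (tab$binding + tab$non_binding), 2L)
  tab$pct_binding[tab$binding + tab$non_binding == 0] <- NA_real_
  rownames(tab) <- NULL
  tab
}

#' Residue counts of the published protein-DNA benchmark datasets
#'
#' Binding / non-binding residue counts of the five community benchmark
#' sets (TR646, TR573, TE46, TE129, TE181) commonly used to evaluate
#' DNA-binding residue predictors, shipped as a plain-text table. Feed to
#' [dataset_stats()] to reproduce the usual class-imbalance summary.
#'
#' @return Data frame with columns `dataset`, `role`, `binding`,
#'   `non_binding`.
#' @export
benchmark_dataset_counts <- function() {
  path <- system.file("extdata", "benchmark_counts.tsv", package = "bindgraph")
  assert_that(nzchar(path), "packaged benchmark_counts.tsv not found",
              "bindgraph_io_error")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write an evaluation report as a delimited text table
#'
#' One row per dataset with columns `Spe, Rec, Pre, F1, MCC, AUC`,
#' mirroring the layout of published benchmark comparisons.
#'
#' @param reports named list of `metrics_report`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(reports, path) {
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(dataset = nm, Spe = r$Spe, Rec = r$Rec, Pre = r$Pre,
               F1 = r$F1, MCC = r$MCC, AUC = r$AUC)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
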