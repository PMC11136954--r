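# Segmentation metric suite. A single K x K confusion matrix (rows = ground
# truth, columns = prediction) is the source for every metric: per-class
# precision, recall, F1 (harmonic mean), IoU, plus overall accuracy, mIoU
# (unweighted mean of per-class IoUs) and FWIoU (ground-truth-frequency
# weighted mean of per-class IoUs). All reported as percentages.

#' Create an empty confusion matrix
#'
#' @param num_classes K, number of classes.
#' @param class_names optional class labels (default `class0`, `class1`,
#'   ...; for K = 3 the dataset names background / bean_seedling / weed).
#' @return K x K numeric matrix of zeros with class `confusion_matrix`.
#' @export
confusion_matrix <- function(num_classes,
                             class_names = NULL) {
  if (is.null(class_names)) {
    class_names <- if (num_classes == 3)
      c("background", "bean_seedling", "weed")
    else paste0("class", seq_len(num_classes) - 1L)
  }
  stopifnot(length(class_names) == num_classes)
  cm <- matrix(0, num_classes, num_classes,
               dimnames = list(truth = class_names, pred = class_names))
  class(cm) <- c("confusion_matrix", "matrix")
  cm
}

#' Accumulate pixel counts into a confusion matrix
#'
#' `cm[t, p]` is incremented for every pixel with ground truth t and
#' prediction p; accumulation is associative and order-independent, so
#' batches may be added in any order. Pixels whose target equals
#' `ignore_index` are skipped.
#'
#' @param cm matrix from [confusion_matrix()] (or a previous accumulation).
#' @param pred,target integer arrays of equal shape with 0-based class
#'   indices.
#' @param ignore_index optional 0-based label excluded from evaluation.
#' @return the updated confusion matrix.
#' @export
cm_accumulate <- function(cm, pred, target, ignore_index = NULL) {
  if (length(pred) != length(target))
    stop("pred and target must have the same number of pixels")
  ig <- if (is.null(ignore_index)) -1L else as.integer(ignore_index)
  out <- confusion_accumulate_cpp(unclass(cm), as.integer(target),
                                  as.integer(pred), ig)
  dimnames(out) <- dimnames(cm)
  class(out) <- class(cm)
  out
}

half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Compute the full metric report from a confusion matrix
#'
#' Per-class TP/FP/FN are read one-vs-rest from the matrix; overall
#' accuracy is the diagonal fraction (the multi-class form of
#' (TP+TN)/(TP+TN+FP+FN)); F1 is the harmonic mean 2PR/(P+R). Ratios with
#' zero denominator are reported as 0 and listed in the `undefined`
#' attribute instead of aborting batch evaluation.
#'
#' @param cm accumulated confusion matrix with a positive total.
#' @return object of class `metrics_report`: list with `per_class` (data
#'   frame of percent precision, recall, f1, iou), `overall_accuracy`,
#'   `miou`, `fwiou` (percent) and `undefined` (character vector naming
#'   0/0 cells).
#' @export
compute_report <- function(cm) {
  cmv <- unclass(cm)
  total <- sum(cmv)
  if (total <= 0) stop("compute_report: empty confusion matrix")
  K <- nrow(cmv)
  tp <- diag(cmv)
  fp <- colSums(cmv) - tp
  fn <- rowSums(cmv) - tp
  undefined <- character(0)
  flag <- function(den, what) {
    if (any(den == 0))
      undefined <<- c(undefined,
                      paste0(what, ":", rownames(cmv)[den == 0]))
    den
  }
  precision <- safe_ratio(tp, flag(tp + fp, "precision"))
  recall <- safe_ratio(tp, flag(tp + fn, "recall"))
  f1 <- safe_ratio(2 * precision * recall, flag(precision + recall, "f1"))
  iou <- safe_ratio(tp, flag(tp + fp + fn, "iou"))
  ni <- rowSums(cmv)                       # ground-truth class frequency
  report <- list(
    per_class = data.frame(class = rownames(cmv) %||% paste0("class", 0:(K - 1)),
                           precision = 100 * precision,
                           recall = 100 * recall,
                           f1 = 100 * f1,
                           iou = 100 * iou,
                           row.names = NULL),
    overall_accuracy = 100 * sum(tp) / total,
    miou = 100 * mean(iou),
    fwiou = 100 * sum(iou * ni) / sum(ni),
    undefined = undefined)
  class(report) <- "metrics_report"
  report
}

#' Flatten a metrics report to one data-frame row
#' @param report a `metrics_report`.
#' @param method optional method label.
#' @return single-row data frame with per-class and aggregate columns.
#' @export
report_row <- function(report, method = "model") {
  pc <- report$per_class
  out <- data.frame(method = method)
  for (k in seq_len(nrow(pc))) {
    cn <- pc$class[k]
    out[[paste0("precision_", cn)]] <- pc$precision[k]
    out[[paste0("recall_", cn)]] <- pc$recall[k]
    out[[paste0("f1_", cn)]] <- pc$f1[k]
  }
  out$overall_accuracy <- report$overall_accuracy
  for (k in seq_len(nrow(pc)))
    out[[paste0("iou_", pc$class[k])]] <- pc$iou[k]
  out$miou <- report$miou
  out$fwiou <- report$fwiou
  out
}

#' Format one or more reports as a fixed-precision text table
#'
#' Rows are methods; columns are the class-wise precision/recall/F1, then
#' overall accuracy, class-wise IoU, mIoU and FWIoU, all printed as percent
#' with two decimals (half-up rounding).
#'
#' @param reports a single `metrics_report` or a named list of them.
#' @return character: the formatted table (one element per line, suitable
#'   for `cat(x, sep = "\n")`); the parsed-back numbers equal the report
#'   values rounded half-up to two decimals.
#' @export
format_metrics_table <- function(reports) {
  if (inherits(reports, "metrics_report")) reports <- list(model = reports)
  if (!length(reports)) stop("need at least one report")
  rows <- do.call(rbind, lapply(names(reports), function(nm)
    report_row(reports[[nm]], nm)))
  num <- vapply(rows[-1], function(col) sprintf("%.2f", half_up(col)),
                character(nrow(rows)))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(rows))
  tab <- cbind(method = rows$method, num)
  colnames(tab) <- colnames(rows)
  widths <- pmax(nchar(colnames(tab)),
                 apply(nchar(tab), 2, max))
  fmt_row <- function(cells) paste(mapply(formatC, cells, width = widths,
                                          MoreArgs = list(flag = "-")),
                                   collapse = "  ")
  c(fmt_row(colnames(tab)), apply(tab, 1, fmt_row))
}

#' Write reports to CSV
#' @param reports named list of `metrics_report` objects (or one report).
#' @param path output CSV file.
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(model = reports)
  rows <- do.call(rbind, lapply(names(reports), function(nm)
    report_row(reports[[nm]], nm)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics_table(list(model = x)), sep = "\n")
  if (length(x$undefined))
    cat("undefined (0/0 reported as 0):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# ---- reference benchmark tables --------------------------------------------

#' Published benchmark tables for the bean-seedling/weed dataset
#'
#' Per-class precision/recall/F1/IoU and aggregate OA/mIoU/FWIoU (percent)
#' reported for EPAnet, its ablation variants and seven comparison networks
#' on the 300-image bean seedling / weed dataset. Used by the
#' internal-consistency checks (printed F1 cells must equal 2PR/(P+R) of
#' their printed precision and recall; printed mIoU cells must equal the
#' mean of the printed per-class IoUs).
#'
#' @return data frame with columns `table` ("ablation" or "comparison"),
#'   `method`, `class`, `precision`, `recall`, `f1`, `oa`, `iou`, `miou`,
#'   `fwiou`.
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_tables.csv", package = "epanet")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Internal-consistency check of the reference tables
#'
#' Recomputes every F1 cell from its printed precision and recall
#' (harmonic mean) and every mIoU cell from the printed per-class IoUs,
#' and returns the absolute deviations from the printed values.
#'
#' @param tables data frame from [reference_tables()].
#' @return data frame with one row per (table, method): `f1_max_abs_err`
#'   (worst F1 cell deviation) and `miou_abs_err`.
#' @export
table_consistency <- function(tables = reference_tables()) {
  keys <- unique(tables[c("table", "method")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    rows <- tables[tables$table == keys$table[i] &
                     tables$method == keys$method[i], ]
    f1_hat <- 2 * rows$precision * rows$recall / (rows$precision + rows$recall)
    data.frame(table = keys$table[i], method = keys$method[i],
               f1_max_abs_err = max(abs(half_up(f1_hat) - rows$f1)),
               miou_abs_err = abs(half_up(mean(rows$iou)) - rows$miou[1]))
  }))
  rownames(out) <- NULL
  out
}
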