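#' Confusion matrix from predictions
#'
#' Counts matrix with rows = true class, columns = predicted class.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param labels Class label order; defaults to the sorted union of both.
#' @return Object of class `fessemg_confusion` (list: `matrix`, `labels`,
#'   `normalized = FALSE`).
#' @export
confusion_from_predictions <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred must have equal length")
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% labels))
    stop_input("labels not covering all observed classes: ",
               paste(setdiff(unique(c(y_true, y_pred)), labels), collapse = ", "))
  m <- table(factor(y_true, levels = labels), factor(y_pred, levels = labels))
  m <- matrix(as.numeric(m), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  structure(list(matrix = m, labels = labels, normalized = FALSE),
            class = "fessemg_confusion")
}

#' Row-normalize a counts confusion matrix to percentages
#' @param cm A `fessemg_confusion` with counts.
#' @return A `fessemg_confusion` with `normalized = TRUE` (rows sum to 100).
#' @export
normalize_confusion <- function(cm) {
  stopifnot(inherits(cm, "fessemg_confusion"), !cm$normalized)
  rs <- rowSums(cm$matrix)
  m <- sweep(cm$matrix, 1, ifelse(rs > 0, rs, 1), "/") * 100
  structure(list(matrix = m, labels = cm$labels, normalized = TRUE),
            class = "fessemg_confusion")
}

#' Wrap a printed row-normalized percentage matrix
#'
#' For ingesting published confusion matrices given in row percentages.
#' Row sums must lie in `[99.5, 100.5]` (printed matrices are rounded);
#' values are NOT re-normalized, so downstream metrics reproduce the
#' printed numbers.
#'
#' @param m Square numeric matrix of row percentages.
#' @param labels Class labels (defaults to rownames).
#' @return A `fessemg_confusion` with `normalized = TRUE`.
#' @export
confusion_from_normalized <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), nrow(m) >= 2)
  if (is.null(labels)) labels <- paste0("class", seq_len(nrow(m)))
  rs <- rowSums(m)
  if (any(rs < 99.5 | rs > 100.5))
    stop_input("row sums outside [99.5, 100.5]: not a row-percentage matrix")
  dimnames(m) <- list(true = labels, predicted = labels)
  structure(list(matrix = m, labels = labels, normalized = TRUE),
            class = "fessemg_confusion")
}

#' @export
print.fessemg_confusion <- function(x, ...) {
  cat("<fessemg_confusion> ", if (x$normalized) "row-%" else "counts",
      ", ", length(x$labels), " classes\n", sep = "")
  print(round(x$matrix, 2))
  invisible(x)
}

#' Precision/recall/F1/accuracy from a counts confusion matrix
#'
#' One-vs-rest TP/FP/FN/TN per class; precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 their harmonic mean, overall accuracy = trace/total (the
#' standard multi-class reduction), all in percent. Zero denominators yield
#' 0 with a `degenerate` flag on that class.
#'
#' @param cm A `fessemg_confusion` with counts.
#' @return Object of class `fessemg_metrics`: data frame with per-class
#'   metrics (percent) and attributes `accuracy` (percent) and
#'   `macro` (unweighted means).
#' @export
metrics_from_counts <- function(cm) {
  stopifnot(inherits(cm, "fessemg_confusion"))
  if (cm$normalized) stop_input("metrics_from_counts expects a counts matrix")
  m <- cm$matrix
  if (length(m) == 0 || sum(m) == 0) stop_input("empty confusion matrix")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- sum(m) - tp - fp - fn
  build_metrics(cm$labels, tp, fp, fn, tn, accuracy = sum(tp) / sum(m) * 100)
}

#' Metrics from a printed row-normalized confusion matrix
#'
#' Under balanced class priors (equal row totals, as in the balanced test
#' sets used here): recall is the diagonal entry, precision is the diagonal
#' divided by its column sum (x100), F1 their harmonic mean, and overall
#' accuracy the mean of the diagonal. This is the arithmetic that links a
#' published row-percentage confusion matrix to its metric table.
#'
#' @param cm A normalized `fessemg_confusion` (see
#'   [confusion_from_normalized()]).
#' @param balanced Must be `TRUE`; the identities above need equal priors.
#' @return A `fessemg_metrics`.
#' @export
metrics_from_normalized <- function(cm, balanced = TRUE) {
  stopifnot(inherits(cm, "fessemg_confusion"), cm$normalized)
  if (!balanced)
    stop_input("metrics_from_normalized requires balanced class priors")
  m <- cm$matrix
  diagv <- diag(m)
  colsum <- colSums(m)
  recall <- diagv
  precision <- ifelse(colsum > 0, diagv / colsum * 100, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  res <- data.frame(class = cm$labels, precision = precision, recall = recall,
                    f1 = f1, degenerate = colsum == 0, row.names = NULL)
  structure(res, class = c("fessemg_metrics", "data.frame"),
            accuracy = mean(diagv),
            macro = c(precision = mean(precision), recall = mean(recall),
                      f1 = mean(f1)))
}

build_metrics <- function(labels, tp, fp, fn, tn, accuracy) {
  precision <- ifelse(tp + fp > 0, tp / (tp + fp) * 100, 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn) * 100, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  res <- data.frame(class = labels, precision = precision, recall = recall,
                    f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn,
                    degenerate = (tp + fp == 0) | (tp + fn == 0),
                    row.names = NULL)
  structure(res, class = c("fessemg_metrics", "data.frame"),
            accuracy = accuracy,
            macro = c(precision = mean(precision), recall = mean(recall),
                      f1 = mean(f1)))
}

#' @export
print.fessemg_metrics <- function(x, ...) {
  cat("<fessemg_metrics> accuracy ", round(attr(x, "accuracy"), 2), "%\n",
      sep = "")
  print.data.frame(cbind(x[, "class", drop = FALSE],
                         round(x[, c("precision", "recall", "f1")], 2)))
  invisible(x)
}

#' Overall accuracy of a metrics report
#' @param metrics A `fessemg_metrics`.
#' @return Accuracy in percent.
#' @export
overall_accuracy <- function(metrics) attr(metrics, "accuracy")

#' Load a published row-percentage confusion matrix shipped with the package
#'
#' The package ships the two printed lower-limb motion confusion matrices
#' (deep model on Hilbert-Huang images, and the 4-TDF LDA baseline) as plain
#' CSV under `inst/extdata`.
#'
#' @param name `"hht_net_motion"` or `"tdf_lda_motion"`.
#' @return A normalized `fessemg_confusion`.
#' @export
published_confusion <- function(name = c("hht_net_motion", "tdf_lda_motion")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("confusion_", name, ".csv"),
                      package = "fessemg", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  confusion_from_normalized(as.matrix(df), labels = rownames(df))
}
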