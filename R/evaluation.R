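#' Confusion matrix in fixed AAMI class order
#'
#' Rows are actual classes, columns predicted, in the fixed order N, V, S,
#' F, Q (or N, V, S for the three-class scheme).
#'
#' @param actual,predicted Equal-length label vectors within the scheme.
#' @param scheme `"five_class"` or `"three_class"`.
#' @return A `confusion_matrix`: integer matrix with class dimnames.
#' @export
confusion_from_predictions <- function(actual, predicted,
                                       scheme = c("five_class", "three_class")) {
  scheme <- match.arg(scheme)
  lev <- aami_classes(scheme)
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have the same length")
  bad <- setdiff(unique(c(actual, predicted)), lev)
  if (length(bad))
    stop("label(s) outside the ", scheme, " scheme: ",
         paste(bad, collapse = " "))
  m <- table(factor(actual, lev), factor(predicted, lev))
  as_confusion(matrix(as.integer(m), length(lev), length(lev),
                      dimnames = list(lev, lev)))
}

#' @rdname confusion_from_predictions
#' @param counts Square non-negative integer matrix with class dimnames in
#'   AAMI order.
#' @return (`as_confusion`) The validated `confusion_matrix`.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (k != ncol(counts) || !k %in% c(3L, 5L))
    stop("confusion matrix must be 3x3 or 5x5")
  lev <- aami_classes(if (k == 5) "five_class" else "three_class")
  if (is.null(dimnames(counts))) dimnames(counts) <- list(lev, lev)
  if (!identical(rownames(counts), lev) || !identical(colnames(counts), lev))
    stop("dimnames must be the AAMI classes in order: ",
         paste(lev, collapse = ","))
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Per-class SEN/FPR/PPV and overall accuracy
#'
#' Computes the AAMI-convention metrics with the class-specific
#' false-positive exclusions customary in inter-patient benchmarking:
#' ventricular false positives do not count fusion or unknown beats
#' predicted as V (`FP_V = C_V - (Vv + Fv + Qv)`), and supraventricular
#' false positives do not count unknown beats predicted as S
#' (`FP_S = C_S - (Ss + Qs)`); the remaining classes use the plain column
#' convention `FP_k = C_k - diag_k`. True negatives are
#' `TN_k = R - (R_k + C_k - diag_k)` with `R` the grand total. Sensitivity
#' is `TP/(TP+FN)`, the false-positive rate `FP/(TN+FP)`, positive
#' predictivity `TP/(TP+FP)` and overall accuracy the diagonal fraction,
#' all as percentages. Because of the V and S exclusions the PPV of those
#' classes differs from the plain column-based value; both are returned
#' (`PPV` uses the exclusions, `PPV_raw` the plain columns). In the
#' three-class scheme the excluded cells involve absent classes, so the two
#' coincide.
#'
#' @param cm A `confusion_matrix`.
#' @return A `class_metrics` object: data.frame of per-class `TP`, `FN`,
#'   `FP`, `TN`, `SEN`, `FPR`, `PPV`, `PPV_raw` (percent) with attribute
#'   `OA` (percent).
#' @export
compute_metrics <- function(cm) {
  cm <- as_confusion(cm)
  if (sum(cm) == 0) stop("undefined metrics: all-zero confusion matrix")
  lev <- rownames(cm)
  R_k <- rowSums(cm)
  C_k <- colSums(cm)
  total <- sum(cm)
  diag_k <- diag(cm)
  fp <- C_k - diag_k
  if ("F" %in% lev) fp[["V"]] <- C_k[["V"]] - (cm["V", "V"] + cm["F", "V"] + cm["Q", "V"])
  if ("Q" %in% lev) fp[["S"]] <- C_k[["S"]] - (cm["S", "S"] + cm["Q", "S"])
  fn <- R_k - diag_k
  tn <- total - (R_k + C_k - diag_k)
  rate <- function(num, den) ifelse(den > 0, 100 * num / den, 0)
  out <- data.frame(
    class = lev,
    TP = as.integer(diag_k), FN = as.integer(fn),
    FP = as.integer(fp), TN = as.integer(tn),
    SEN = rate(diag_k, R_k),
    FPR = rate(fp, tn + fp),
    PPV = rate(diag_k, diag_k + fp),
    PPV_raw = rate(diag_k, C_k),
    row.names = lev)
  attr(out, "OA") <- 100 * sum(diag_k) / total
  class(out) <- c("class_metrics", "data.frame")
  out
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.2f%%\n", attr(x, "OA")))
  df <- data.frame(`SEN%` = round(x$SEN, 1), `FPR%` = round(x$FPR, 1),
                   `PPV%` = round(x$PPV, 1), row.names = x$class,
                   check.names = FALSE)
  print(df)
  invisible(x)
}

#' Rounded metric report
#'
#' A plain-list report of the metrics, with per-class values rounded to one
#' decimal and the overall accuracy to two, mirroring the precision at
#' which such tables are customarily published. Written to JSON when `path`
#' is given.
#'
#' @param metrics A `class_metrics` from [compute_metrics()].
#' @param path Optional JSON output path.
#' @return Invisibly (or visibly when `path` is `NULL`) a list with `OA`
#'   and a per-class data.frame of `SEN`, `FPR`, `PPV` (and `PPV_raw`).
#' @export
metrics_report <- function(metrics, path = NULL) {
  stopifnot(inherits(metrics, "class_metrics"))
  rep <- list(
    OA = round(attr(metrics, "OA"), 2),
    per_class = data.frame(
      class = metrics$class,
      SEN = round(metrics$SEN, 1),
      FPR = round(metrics$FPR, 1),
      PPV = round(metrics$PPV, 1),
      PPV_raw = round(metrics$PPV_raw, 1)))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(rep))
  }
  rep
}

#' Read a metric report back from JSON
#'
#' @param path JSON file written by [metrics_report()].
#' @return The report list.
#' @export
read_metrics_report <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write / read a confusion matrix as CSV
#'
#' CSV with class labels as header row and first column.
#'
#' @param cm A `confusion_matrix` (write) or path (read).
#' @param path Output path.
#' @export
write_confusion_csv <- function(cm, path) {
  cm <- as_confusion(cm)
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion(as.matrix(df))
}

#' Bundled reference confusion matrices
#'
#' Published confusion matrices for product-rule voting ensembles evaluated
#' on the MIT-BIH DS2 inter-patient test set, shipped as plain CSV. They
#' serve as fixed inputs for validating the metric conventions of
#' [compute_metrics()] against the corresponding published metric tables,
#' without requiring the database itself. Available names:
#' `"voting_j48_lda_nb"` (5-class), `"voting_j48c_nb_lda"` (5-class) and
#' `"voting_j48_lda_nb_3class"`.
#'
#' @param name Reference matrix name.
#' @return A `confusion_matrix`.
#' @export
reference_confusion <- function(name = c("voting_j48_lda_nb",
                                         "voting_j48c_nb_lda",
                                         "voting_j48_lda_nb_3class")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("confusion_", name, ".csv"),
                      package = "ecgvote", mustWork = TRUE)
  read_confusion_csv(path)
}
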