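.emClasses <- c("woodland", "shrubland", "grassland")

#' Build an error matrix from mapped and reference labels
#'
#' Cross-tabulates the mapped (predicted) class against the reference
#' class at assessment sites. Rows are the mapped class and columns the
#' reference class, in woodland, shrubland, grassland order. Mapped
#' "unclassified" sites are tallied separately and excluded from the 3x3
#' table; any other label outside the legend is an error.
#'
#' @param predicted,reference equal-length character vectors of class
#'   labels at the assessment sites.
#' @return An \linkS4class{ErrorMatrix}.
#' @export
#' @examples
#' em <- errorMatrix(c("woodland", "grassland"), c("woodland", "grassland"))
#' overallAccuracy(em)  # 100
errorMatrix <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  if (!length(predicted)) stop("empty label vectors")
  predicted <- as.character(predicted); reference <- as.character(reference)
  badRef <- setdiff(unique(reference), .emClasses)
  if (length(badRef))
    stop("unknown reference label(s): ", paste(badRef, collapse = ", "))
  badPred <- setdiff(unique(predicted), c(.emClasses, "unclassified"))
  if (length(badPred))
    stop("unknown mapped label(s): ", paste(badPred, collapse = ", "))
  uncl <- predicted == "unclassified"
  counts <- table(factor(predicted[!uncl], levels = .emClasses),
                  factor(reference[!uncl], levels = .emClasses))
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(mapped = .emClasses, reference = .emClasses))
  new("ErrorMatrix", counts = m, unclassified = sum(uncl))
}

#' Build an error matrix directly from a 3x3 count table
#'
#' For published count tables: rows mapped, columns reference, classes in
#' woodland, shrubland, grassland order.
#'
#' @param counts 3x3 nonnegative matrix of counts.
#' @param unclassified count of reference sites left unclassified.
#' @return An \linkS4class{ErrorMatrix}.
#' @export
errorMatrixFromCounts <- function(counts, unclassified = 0L) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(mapped = .emClasses, reference = .emClasses)
  storage.mode(counts) <- "integer"
  new("ErrorMatrix", counts = counts, unclassified = as.integer(unclassified))
}

setMethod("show", "ErrorMatrix", function(object) {
  cat("ErrorMatrix (rows = mapped, cols = reference)\n")
  print(object@counts)
  cat(sprintf("Overall accuracy: %.2f%%", overallAccuracy(object)))
  if (object@unclassified > 0L)
    cat(sprintf("  (%d unclassified site(s) excluded)", object@unclassified))
  cat("\n")
  invisible(NULL)
})

#' Overall accuracy of an error matrix
#'
#' 100 times the trace over the grand total: the percentage of assessment
#' sites whose mapped class equals their reference class.
#'
#' @param m an \linkS4class{ErrorMatrix}.
#' @return Percentage in [0, 100].
#' @export
overallAccuracy <- function(m) {
  stopifnot(is(m, "ErrorMatrix"))
  total <- sum(m@counts)
  if (total == 0) stop("error matrix has zero grand total")
  100 * sum(diag(m@counts)) / total
}

#' Per-class omission and commission errors
#'
#' Omission error for class j is the share of reference sites of class j
#' not mapped as j (column-wise; 100 minus producer's accuracy).
#' Commission error for class i is the share of sites mapped as i whose
#' reference class differs (row-wise; 100 minus user's accuracy). A class
#' with a zero column (or row) total has undefined omission (commission),
#' reported as NA.
#'
#' @param m an \linkS4class{ErrorMatrix}.
#' @return data.frame with columns class, omission_pct, commission_pct.
#' @export
omissionCommission <- function(m) {
  stopifnot(is(m, "ErrorMatrix"))
  cm <- m@counts
  colTot <- colSums(cm); rowTot <- rowSums(cm); dg <- diag(cm)
  om <- ifelse(colTot > 0, 100 * (colTot - dg) / colTot, NA_real_)
  co <- ifelse(rowTot > 0, 100 * (rowTot - dg) / rowTot, NA_real_)
  data.frame(class = rownames(cm), omission_pct = as.numeric(om),
             commission_pct = as.numeric(co), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Support vector machine baseline classifier
#'
#' A generic supervised baseline to compare the rule-based classifier
#' against: a soft-margin SVM with a radial-basis kernel and unit-variance
#' feature scaling (via \pkg{e1071}), trained on per-pixel feature columns
#' and applied to test sites. Deterministic given the seed and inputs.
#'
#' @param train data.frame with a \code{class} column and numeric feature
#'   columns.
#' @param test data.frame with the same feature columns.
#' @param features character vector of feature column names (default: all
#'   shared numeric columns except class/row/col bookkeeping).
#' @param kernel SVM kernel, default "radial".
#' @param cost soft-margin cost parameter.
#' @param seed integer RNG seed.
#' @return Character vector of predicted labels for \code{test} rows.
#' @export
svmBaseline <- function(train, test, features = NULL, kernel = "radial",
                        cost = 1, seed = 1L) {
  if (length(unique(train$class)) < 2L)
    stop("SVM baseline needs at least two classes in the training data")
  if (is.null(features))
    features <- setdiff(names(train)[vapply(train, is.numeric, logical(1))],
                        c("row", "col"))
  missing <- setdiff(features, names(test))
  if (length(missing))
    stop("test data lacks feature column(s): ", paste(missing, collapse = ", "))
  set.seed(seed)
  fit <- e1071::svm(x = as.matrix(train[features]),
                    y = factor(train$class), kernel = kernel, cost = cost,
                    scale = TRUE)
  as.character(stats::predict(fit, as.matrix(test[features])))
}
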