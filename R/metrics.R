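#' Confusion matrix with responders as the positive class
#'
#' Tallies predicted against true labels. Throughout the package the
#' responder class (\code{"RES"}) is the positive class, so \code{tp} counts
#' responders called responders and \code{tn} non-responders called
#' non-responders.
#'
#' @param predicted character vector of predicted labels, named by sample id.
#' @param truth character vector of true labels, named by sample id. Must
#'   contain exactly the same sample ids as \code{predicted}.
#' @param positive label treated as positive; default \code{"RES"}.
#'
#' @return An object of class \code{"confusion_matrix"}: a list with integer
#'   fields \code{tp}, \code{fn}, \code{fp}, \code{tn} and the
#'   \code{positive} label.
#' @seealso [compute_metrics()]
#' @export
confusion <- function(predicted, truth, positive = "RES") {
  if (is.null(names(predicted)) || is.null(names(truth))) {
    stop("'predicted' and 'truth' must be named by sample id")
  }
  if (!setequal(names(predicted), names(truth)) ||
      anyDuplicated(names(predicted)) || anyDuplicated(names(truth))) {
    stop("sample ids of 'predicted' and 'truth' do not match")
  }
  predicted <- predicted[names(truth)]
  pos_true <- truth == positive
  pos_pred <- predicted == positive
  out <- list(
    tp = sum(pos_true & pos_pred),
    fn = sum(pos_true & !pos_pred),
    fp = sum(!pos_true & pos_pred),
    tn = sum(!pos_true & !pos_pred),
    positive = positive
  )
  class(out) <- "confusion_matrix"
  out
}

#' Construct a confusion matrix from its four counts
#'
#' Convenience constructor when the counts are known directly (e.g. from a
#' published performance table).
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @param positive positive-class label; default \code{"RES"}.
#' @return A \code{"confusion_matrix"} object.
#' @export
confusion_counts <- function(tp, fn, fp, tn, positive = "RES") {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be non-negative integers")
  }
  out <- list(tp = as.integer(tp), fn = as.integer(fn),
              fp = as.integer(fp), tn = as.integer(tn), positive = positive)
  class(out) <- "confusion_matrix"
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive = ", x$positive, ")\n", sep = "")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c(x$positive, paste0("non-", x$positive)),
                              predicted = c(x$positive, paste0("non-", x$positive))))
  print(m)
  invisible(x)
}

#' Classification performance statistics
#'
#' Computes the five statistics used to report discrimination performance:
#' accuracy, sensitivity, specificity, precision and F1 measure, with
#' responders as the positive class. A ratio with zero denominator is
#' reported as 0 and flagged in \code{undefined}, keeping downstream
#' selection criteria total functions.
#'
#' @param m a \code{"confusion_matrix"} object.
#' @return An object of class \code{"classification_metrics"}: list with
#'   \code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{precision}, \code{f1}, and \code{undefined} (character vector of
#'   metrics whose denominator was zero).
#' @export
compute_metrics <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  total <- m$tp + m$fn + m$fp + m$tn
  if (total == 0) stop("empty confusion matrix")
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(0)
    }
    num / den
  }
  sens <- ratio(m$tp, m$tp + m$fn, "sensitivity")
  spec <- ratio(m$tn, m$tn + m$fp, "specificity")
  prec <- ratio(m$tp, m$tp + m$fp, "precision")
  f1 <- ratio(2 * prec * sens, prec + sens, "f1")
  out <- list(
    accuracy = (m$tp + m$tn) / total,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    f1 = f1,
    undefined = undefined
  )
  class(out) <- "classification_metrics"
  out
}

#' @export
print.classification_metrics <- function(x, digits = 2, ...) {
  v <- unlist(x[c("accuracy", "sensitivity", "specificity", "precision", "f1")])
  # half-up rounding to match conventional report tables
  print(floor(v * 10^digits + 0.5) / 10^digits)
  if (length(x$undefined)) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Round half-up for display
#'
#' Report tables conventionally round half-up (0.875 -> 0.88) rather than
#' with R's banker's rounding.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}
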