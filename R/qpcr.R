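#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(concentration) over a dilution
#' series. A valid amplification gives a negative slope (around -3.32
#' cycles per decade at 100% efficiency); a non-negative fitted slope is
#' flagged rather than silently accepted.
#'
#' @param concentration_fM strictly positive, distinct concentrations (fM);
#'   at least 3 points.
#' @param cq measured quantification cycles, same length.
#' @return An object of class \code{"standard_curve"}: \code{slope}
#'   (cycles/decade), \code{intercept} (Cq at 1 fM), \code{r_squared}, and
#'   \code{slope_warning} (TRUE when slope >= 0).
#' @export
fit_standard_curve <- function(concentration_fM, cq) {
  if (length(concentration_fM) < 3) stop("need at least 3 dilution points")
  if (length(cq) != length(concentration_fM)) stop("lengths differ")
  if (any(concentration_fM <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(concentration_fM)) stop("duplicate concentrations in dilution series")
  lc <- log10(concentration_fM)
  fit <- stats::lm(cq ~ lc)
  slope <- unname(stats::coef(fit)[2])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  warn <- slope >= 0
  if (warn) warning("standard curve slope is non-negative; amplification suspect")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, slope_warning = warn),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Cq = %.4f %+.4f * log10(fM)  (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  if (x$slope_warning) cat("WARNING: non-negative slope\n")
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the calibration line: \code{concentration = 10^((cq -
#' intercept)/slope)}, in fM.
#'
#' @param curve a \code{"standard_curve"} with negative slope.
#' @param cq numeric vector of quantification cycles.
#' @return Concentrations in fM.
#' @export
quantify <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("cannot quantify from a non-negative slope")
  10^((cq - curve$intercept) / curve$slope)
}

#' Quantify a duplicate-measurement plate
#'
#' Each replicate Cq is converted to a concentration through its gene's
#' standard curve; replicates of a sample x gene well are then averaged on
#' the concentration scale (set \code{combine = "cq"} to average Cq values
#' before converting instead).
#'
#' @param curves named list of \code{"standard_curve"} objects, one per gene.
#' @param plate data frame with columns \code{sample_id}, \code{gene},
#'   \code{replicate}, \code{cq}.
#' @param combine \code{"concentration"} (default) or \code{"cq"}.
#' @return Data frame \code{sample_id}, \code{gene}, \code{quantity_fM}.
#' @export
quantify_plate <- function(curves, plate, combine = c("concentration", "cq")) {
  combine <- match.arg(combine)
  need <- setdiff(unique(plate$gene), names(curves))
  if (length(need)) stop("no standard curve for gene(s): ", paste(need, collapse = ", "))
  split_idx <- interaction(plate$sample_id, plate$gene, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(plate)), split_idx), function(i) {
    g <- plate$gene[i[1]]
    q <- if (combine == "concentration") {
      mean(quantify(curves[[g]], plate$cq[i]))
    } else {
      quantify(curves[[g]], mean(plate$cq[i]))
    }
    data.frame(sample_id = plate$sample_id[i[1]], gene = g, quantity_fM = q,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference-gene fold changes anchored at the responder mean
#'
#' Each sample's gene quantity is divided by the same sample's B2M
#' (internal-control) quantity; the per-gene ratios are then divided by
#' their mean over responder samples, so responders average exactly 1. Any
#' common rescaling of a sample's quantities cancels in the B2M ratio.
#'
#' @param quantities numeric matrix, samples x genes, of absolute
#'   quantities (fM); rows named by sample id.
#' @param b2m named numeric vector of B2M quantities per sample, all > 0.
#' @param labels named character vector of \code{"RES"}/\code{"NRES"}.
#' @return Numeric matrix (samples x genes) of fold changes, class
#'   \code{"fold_change_table"}.
#' @export
fold_changes <- function(quantities, b2m, labels) {
  quantities <- as.matrix(quantities)
  samples <- rownames(quantities)
  if (is.null(samples)) stop("'quantities' must have sample row names")
  bad <- samples[!(samples %in% names(b2m)) | b2m[samples] <= 0 |
                   is.na(b2m[samples])]
  if (length(bad)) {
    stop("missing or non-positive B2M quantity for sample(s): ",
         paste(bad, collapse = ", "))
  }
  ratio <- quantities / b2m[samples]
  res <- names(labels)[labels == "RES"]
  if (!length(intersect(res, samples))) stop("no responder samples to anchor at")
  anchor <- colMeans(ratio[intersect(samples, res), , drop = FALSE])
  fc <- sweep(ratio, 2, anchor, "/")
  class(fc) <- c("fold_change_table", class(fc))
  fc
}

#' Compare fold changes between groups with Holm correction
#'
#' Two-sided unpaired Student's t-test (pooled variance) per gene, with
#' Holm step-down adjustment across the tested gene family. A gene whose
#' pooled variance is zero gets p = 1 with a warning.
#'
#' @param fc a samples x genes matrix (e.g. from [fold_changes()]).
#' @param labels named \code{"RES"}/\code{"NRES"} vector covering the rows.
#' @return Data frame \code{gene}, \code{t}, \code{p}, \code{p_holm}.
#' @export
compare_groups <- function(fc, labels) {
  fc <- as.matrix(fc)
  labels <- labels[rownames(fc)]
  if (any(table(labels) < 2)) stop("each group needs at least 2 samples")
  res <- labels == "RES"
  stat <- p <- numeric(ncol(fc))
  for (j in seq_len(ncol(fc))) {
    a <- fc[res, j]
    b <- fc[!res, j]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      warning("zero pooled variance for gene '", colnames(fc)[j], "'; p set to 1")
      stat[j] <- 0
      p[j] <- 1
      next
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    stat[j] <- unname(tt$statistic)
    p[j] <- tt$p.value
  }
  data.frame(gene = colnames(fc), t = stat, p = p,
             p_holm = stats::p.adjust(p, method = "holm"),
             row.names = NULL, stringsAsFactors = FALSE)
}
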