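#' Fit a quantile discretization scheme
#'
#' Each marker's continuous range is divided into a fixed number of
#' exclusive divisions. Interior cut points are equal-frequency quantiles of
#' the pooled training values, so the scheme is scale-free: any strictly
#' monotone transform of the raw values leaves all division assignments
#' unchanged. End divisions are unbounded.
#'
#' @param x numeric matrix of training values, samples in rows, markers in
#'   columns (column names are marker ids).
#' @param divisions integer scalar or per-marker vector of division counts
#'   (each >= 2). Default 2 divisions per marker.
#'
#' @return An object of class \code{"discretization_scheme"}: a named list
#'   of strictly increasing interior cut-point vectors, one per marker
#'   (length \code{divisions - 1}).
#' @examples
#' sch <- fit_discretization(cbind(m1 = c(1, 2, 3, 4)), divisions = 2)
#' sch$m1  # single cut at 2.5
#' @export
fit_discretization <- function(x, divisions = 2L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  m <- ncol(x)
  divisions <- rep_len(as.integer(divisions), m)
  if (any(divisions < 2L)) stop("each marker needs at least 2 divisions")
  cuts <- vector("list", m)
  names(cuts) <- colnames(x)
  for (j in seq_len(m)) {
    v <- x[, j]
    if (anyNA(v)) stop("missing values in marker '", colnames(x)[j], "'")
    if (length(unique(v)) < divisions[j]) {
      stop("marker '", colnames(x)[j], "' has fewer than ", divisions[j],
           " distinct training values; cannot place ", divisions[j] - 1,
           " quantile cuts")
    }
    probs <- seq_len(divisions[j] - 1L) / divisions[j]
    cj <- unname(stats::quantile(v, probs = probs, type = 7))
    if (any(diff(cj) <= 0) && length(cj) > 1L) {
      stop("quantile cuts for marker '", colnames(x)[j],
           "' are not strictly increasing; too few distinct values")
    }
    cuts[[j]] <- cj
  }
  structure(cuts, class = "discretization_scheme", divisions = divisions)
}

#' Discretize marker values against a fitted scheme
#'
#' Maps each raw value to its division index. A value exactly equal to a cut
#' point goes to the lower division (divisions are left-closed from above,
#' i.e. division d is (c_{d-1}, c_d]).
#'
#' @param scheme a \code{"discretization_scheme"}.
#' @param x numeric matrix (samples x markers, marker columns matching the
#'   scheme) or a single named numeric vector of one value per marker.
#' @return Integer matrix of division indices with the same dimnames as the
#'   input (a vector input yields a one-row matrix).
#' @export
discretize <- function(scheme, x) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- names(scheme)
  if (!all(names(scheme) %in% colnames(x))) {
    stop("missing marker value(s): ",
         paste(setdiff(names(scheme), colnames(x)), collapse = ", "))
  }
  x <- x[, names(scheme), drop = FALSE]
  if (anyNA(x)) stop("missing marker values cannot be discretized")
  d <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_along(scheme)) {
    # left.open: interval (cut_{d-1}, cut_d], so a value at a cut falls low
    d[, j] <- findInterval(x[, j], scheme[[j]], left.open = TRUE) + 1L
  }
  d
}

#' Fit a discrete Bayes model from discretized training samples
#'
#' Tallies, for each class, marker and division, the number of training
#' samples of that class whose marker falls in that division. Class 1 is
#' the responder class (RES) and class 2 the non-responder class (NRES);
#' prior probabilities are fixed equal. The smoothing constant \code{eps}
#' is added to every count inside the decision rule so that divisions never
#' seen in training do not produce undefined posteriors.
#'
#' @param d integer matrix of division indices (samples x markers), as
#'   returned by [discretize()].
#' @param labels character vector of class labels per sample (rows of
#'   \code{d}), containing both classes.
#' @param scheme the \code{"discretization_scheme"} the indices came from.
#' @param eps additive smoothing constant, >= 0. Default 0.5; \code{eps = 0}
#'   reproduces the unsmoothed counting rule exactly.
#' @param classes length-2 character vector, positive (RES) class first.
#' @param conditional \code{"cross_marker"} (default) normalizes each
#'   per-marker conditional by the summed counts of the sample's observed
#'   divisions across *all* markers; \code{"per_marker"} uses the standard
#'   naive-Bayes normalization over the divisions of the marker itself. See
#'   the methods vignette for why both are offered.
#'
#' @return An object of class \code{"discrete_bayes_model"}.
#' @export
fit_model <- function(d, labels, scheme, eps = 0.5,
                      classes = c("RES", "NRES"),
                      conditional = c("cross_marker", "per_marker")) {
  conditional <- match.arg(conditional)
  stopifnot(inherits(scheme, "discretization_scheme"))
  d <- as.matrix(d)
  if (nrow(d) != length(labels)) stop("one label per training sample required")
  if (eps < 0) stop("'eps' must be >= 0")
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls)) {
    stop("class absent from training labels: ", paste(missing_cls, collapse = ", "))
  }
  ndiv <- attr(scheme, "divisions")
  counts <- vector("list", length(scheme))
  names(counts) <- names(scheme)
  for (j in seq_along(scheme)) {
    tab <- matrix(0L, ndiv[j], 2L,
                  dimnames = list(division = seq_len(ndiv[j]), class = classes))
    for (i in 1:2) {
      t_i <- tabulate(d[labels == classes[i], j], nbins = ndiv[j])
      tab[, i] <- as.integer(t_i)
    }
    counts[[j]] <- tab
  }
  structure(
    list(scheme = scheme, counts = counts, classes = classes,
         n_class = c(sum(labels == classes[1]), sum(labels == classes[2])),
         eps = eps, priors = c(0.5, 0.5), conditional = conditional),
    class = "discrete_bayes_model"
  )
}

# Log class-conditional likelihoods for a matrix of discretized samples.
# Returns an n x 2 matrix of log P(x | class); -Inf where the (unsmoothed)
# likelihood is zero.
db_loglik <- function(model, d) {
  d <- as.matrix(d)
  m <- length(model$counts)
  if (ncol(d) != m) stop("sample has ", ncol(d), " markers; model expects ", m)
  eps <- model$eps
  out <- matrix(NA_real_, nrow(d), 2L)
  for (i in 1:2) {
    n_at <- vapply(seq_len(m), function(j) {
      dj <- d[, j]
      if (any(dj < 1L | dj > nrow(model$counts[[j]]))) {
        stop("division index out of range for marker '", names(model$counts)[j], "'")
      }
      model$counts[[j]][dj, i]
    }, numeric(nrow(d)))
    n_at <- matrix(n_at, nrow = nrow(d))
    if (model$conditional == "cross_marker") {
      denom <- rowSums(n_at + eps)           # per sample, shared by markers
      ll <- rowSums(log(n_at + eps)) - m * log(denom)
      ll[denom == 0] <- -Inf                 # 0/0: no training mass -> zero likelihood
      out[, i] <- ll
    } else {
      denom <- vapply(seq_len(m), function(j) sum(model$counts[[j]][, i] + eps),
                      numeric(1))            # per marker, constant in sample
      if (any(denom == 0)) {                 # class has no training mass
        out[, i] <- -Inf
      } else {
        out[, i] <- rowSums(log(n_at + eps)) - sum(log(denom))
      }
    }
  }
  out
}

#' Posterior class probabilities under a discrete Bayes model
#'
#' For each class the per-marker conditional probabilities of the sample's
#' observed divisions are multiplied together; the posterior is the
#' normalized product (equal priors cancel).
#'
#' @param model a \code{"discrete_bayes_model"}.
#' @param d integer vector of division indices (one per marker) or a matrix
#'   of samples x markers.
#' @return A numeric vector of two probabilities (named by class), or a
#'   matrix with one row per sample. Rows sum to 1.
#' @export
posterior <- function(model, d) {
  stopifnot(inherits(model, "discrete_bayes_model"))
  vec <- is.null(dim(d))
  if (vec) d <- matrix(as.integer(d), nrow = 1)
  ll <- db_loglik(model, d)
  bad <- !is.finite(ll[, 1]) & !is.finite(ll[, 2])
  if (any(bad)) {
    stop("both class-conditional likelihoods are zero for sample(s) ",
         paste(which(bad), collapse = ", "),
         "; use a smoothing constant eps > 0")
  }
  mx <- pmax(ll[, 1], ll[, 2])
  w <- exp(ll - mx)          # log-sum-exp stabilization
  p <- w / rowSums(w)
  colnames(p) <- model$classes
  if (vec) p[1, ] else p
}

#' Classify samples by maximum posterior probability
#'
#' Assigns each sample to the class with the larger posterior. An exact tie
#' is resolved deterministically in favor of the responder class and
#' flagged.
#'
#' @inheritParams posterior
#' @return A data frame with columns \code{p_res}, \code{p_nres},
#'   \code{label} and \code{tie} (one row per sample; row names carry sample
#'   ids when the input has them).
#' @export
classify <- function(model, d) {
  vec <- is.null(dim(d))
  if (vec) d <- matrix(as.integer(d), nrow = 1)
  p <- posterior(model, d)
  tie <- abs(p[, 1] - p[, 2]) <= 1e-12
  label <- ifelse(tie | p[, 1] > p[, 2], model$classes[1], model$classes[2])
  data.frame(p_res = p[, 1], p_nres = p[, 2], label = label, tie = tie,
             row.names = rownames(d), stringsAsFactors = FALSE)
}

#' @export
print.discrete_bayes_model <- function(x, ...) {
  cat("Discrete Bayes model:", length(x$counts), "marker(s),",
      paste(x$classes, x$n_class, collapse = " / "),
      "training samples\n")
  cat("smoothing eps =", x$eps, "| conditional normalization:",
      x$conditional, "\n")
  invisible(x)
}
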