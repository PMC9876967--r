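#' TMM effective size factors
#'
#' Computes per-sample normalization factors by the trimmed mean of
#' M-values: the composition factor is a doubly trimmed (30% on M, 5% on A),
#' precision-weighted mean of per-gene log ratios against a reference
#' sample (the one whose upper-quartile fraction is closest to the mean),
#' with genes that are zero in either compared sample excluded. The factor
#' returned for each sample is its *effective* size — library size times
#' the composition factor — rescaled so the factors have geometric mean 1.
#' Model offsets downstream are simply \code{log(factor)}.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return An object of class \code{"tmm_factors"}: named numeric vector of
#'   positive factors with geometric mean 1, with the reference sample id
#'   in attribute \code{"reference"}.
#' @export
compute_tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  libsize <- colSums(counts)
  if (any(libsize <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[libsize <= 0], collapse = ", "))
  }
  comp <- edgeR::calcNormFactors(counts, method = "TMM",
                                 logratioTrim = 0.30, sumTrim = 0.05)
  # same reference rule as the TMM definition: upper-quartile of the
  # library-size-scaled counts closest to the mean upper-quartile
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / libsize
  ref <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  eff <- libsize * comp
  eff <- eff / exp(mean(log(eff)))
  structure(stats::setNames(eff, colnames(counts)),
            class = "tmm_factors", reference = ref)
}

# Method-of-moments NB dispersion from normalized counts, pooled within
# groups. Var(y/f) = mu * mean(1/f) + phi * mu^2, hence the inv_f_mean term.
mom_dispersion <- function(z, groups, inv_f_mean = 1, floor = 1e-8) {
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    zg <- z[groups == g]
    if (length(zg) < 2) next
    mu <- mean(zg)
    if (mu <= 0) next
    num <- num + (stats::var(zg) - mu * inv_f_mean) / mu^2 * (length(zg) - 1)
    den <- den + (length(zg) - 1)
  }
  if (den == 0) return(floor)
  max(num / den, floor)
}

nb_fit_deviance <- function(y, offset, groups, theta) {
  fam <- MASS::negative.binomial(theta)
  null <- suppressWarnings(
    stats::glm.fit(matrix(1, length(y)), y, offset = offset, family = fam,
                   control = list(maxit = 50))
  )
  alt_dev <- 0
  for (g in unique(groups)) {
    i <- groups == g
    fit <- suppressWarnings(
      stats::glm.fit(matrix(1, sum(i)), y[i], offset = offset[i], family = fam,
                     control = list(maxit = 50))
    )
    alt_dev <- alt_dev + fit$deviance
  }
  c(null = null$deviance, alt = alt_dev)
}

#' Two-group negative-binomial likelihood-ratio test per gene
#'
#' For every gene, a one-mean (null) negative-binomial model is compared
#' with a two-mean (one mean per group) model by a likelihood-ratio test;
#' both use \code{log(factor)} offsets from [compute_tmm_factors()] and a
#' gene-wise dispersion estimated by method of moments on the normalized
#' counts. Each gene's moment estimate is floored at the median of the
#' per-gene estimates (and at 1e-8): small-sample moment estimates skew
#' low, and an underestimated dispersion makes the chi-square reference
#' anti-conservative. P-values come from the chi-square distribution
#' with 1 degree of freedom. The log2 fold change is the log2 ratio of the
#' non-responder to the responder normalized group mean, with a 0.5
#' pseudo-count on each mean. Genes with zero counts in every sample get
#' p = 1 and log2FC = 0.
#'
#' @param counts genes x samples count matrix.
#' @param labels named character vector of \code{"RES"}/\code{"NRES"}
#'   labels covering the samples.
#' @param factors a \code{"tmm_factors"} object for the same samples.
#' @param p_threshold,fc_threshold thresholds recorded in the
#'   \code{passes_filter} column (p < p_threshold and linear fold change
#'   > fc_threshold in either direction).
#' @return A data frame with one row per gene: \code{gene}, \code{log2fc},
#'   \code{pvalue}, \code{mean_count} (raw mean over all samples),
#'   \code{passes_filter}.
#' @export
de_test <- function(counts, labels, factors, p_threshold = 0.01,
                    fc_threshold = 1.5) {
  counts <- as.matrix(counts)
  labels <- labels[colnames(counts)]
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two label levels required")
  if (any(table(labels) < 2)) stop("each group needs at least 2 samples")
  f <- as.numeric(factors)[match(colnames(counts), names(factors))]
  if (anyNA(f)) stop("factors do not cover all samples")
  offset <- log(f)
  z <- sweep(counts, 2, f, "/")              # normalized counts
  inv_f_mean <- mean(1 / f)
  res_idx <- labels == "RES"
  ng <- nrow(counts)
  pvalue <- numeric(ng)
  log2fc <- numeric(ng)
  degenerate <- rowSums(counts) == 0
  phi_raw <- rep(NA_real_, ng)
  for (g in which(!degenerate)) {
    phi_raw[g] <- mom_dispersion(z[g, ], labels, inv_f_mean)
  }
  # per-gene moment estimates are noisy at small n and skew low, which makes
  # the LRT liberal; flooring each estimate at the across-gene median keeps
  # the test calibrated while leaving high-dispersion genes their own value
  phi_floor <- if (all(degenerate)) 1e-8 else stats::median(phi_raw, na.rm = TRUE)
  for (g in seq_len(ng)) {
    y <- counts[g, ]
    if (degenerate[g]) {
      pvalue[g] <- 1
      log2fc[g] <- 0
      next
    }
    zg <- z[g, ]
    log2fc[g] <- log2((mean(zg[!res_idx]) + 0.5) / (mean(zg[res_idx]) + 0.5))
    phi <- max(phi_raw[g], phi_floor, 1e-8)
    dev <- nb_fit_deviance(y, offset, labels, theta = 1 / phi)
    lr <- max(dev["null"] - dev["alt"], 0)
    pvalue[g] <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  }
  mean_count <- rowMeans(counts)
  data.frame(
    gene = rownames(counts) %||% paste0("g", seq_len(ng)),
    log2fc = log2fc,
    pvalue = pvalue,
    mean_count = mean_count,
    passes_filter = pvalue < p_threshold & 2^abs(log2fc) > fc_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

order_de <- function(results) {
  order(results$pvalue, -abs(results$log2fc), results$gene)
}

#' Candidate genes passing the significance and fold-change filter
#'
#' Genes with p below the threshold and linear fold change above the
#' threshold in either direction, ordered by ascending p (ties: larger
#' absolute log2FC, then gene id).
#'
#' @param results data frame from [de_test()].
#' @param p_threshold p-value cut, default 0.01.
#' @param fc_threshold linear fold-change cut, default 1.5; a gene passes
#'   when \code{2^abs(log2fc) > fc_threshold}.
#' @return Character vector of gene ids.
#' @export
filter_candidates <- function(results, p_threshold = 0.01, fc_threshold = 1.5) {
  if (p_threshold <= 0 || fc_threshold <= 0) stop("thresholds must be > 0")
  keep <- results$pvalue < p_threshold & 2^abs(results$log2fc) > fc_threshold
  passing <- results[keep, , drop = FALSE]
  passing$gene[order_de(passing)]
}

#' Select validation targets for qPCR follow-up
#'
#' Among filter-passing genes whose mean raw count is at least
#' \code{min_mean_count}, the \code{top_n} genes with the smallest p-values
#' (ties: larger absolute log2FC, then gene id). Fewer are returned if
#' fewer qualify.
#'
#' @inheritParams filter_candidates
#' @param min_mean_count minimum mean raw count, default 50.
#' @param top_n number of targets, default 10.
#' @return Character vector of gene ids, ascending p.
#' @export
select_validation_targets <- function(results, p_threshold = 0.01,
                                      fc_threshold = 1.5,
                                      min_mean_count = 50, top_n = 10) {
  if (!nrow(results)) stop("'results' must be non-empty")
  keep <- results$pvalue < p_threshold &
    2^abs(results$log2fc) > fc_threshold &
    results$mean_count >= min_mean_count
  passing <- results[keep, , drop = FALSE]
  ids <- passing$gene[order_de(passing)]
  utils::head(ids, top_n)
}
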