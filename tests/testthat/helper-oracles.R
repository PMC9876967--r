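# Independent oracles used across the suite. These deliberately re-derive
# results by the most literal route available (scalar loops, closed forms)
# and never call the package functions they are used to check.

# Literal scalar transcription of the discrete Bayes decision rule: for each
# class, each marker's conditional is the count at the sample's observed
# division over the summed counts, across all markers, of the observed
# divisions; the class-conditional is the plain product and the posterior the
# normalized product (equal priors).
oracle_posterior_cross <- function(counts, d, eps) {
  m <- length(counts)
  lik <- numeric(2)
  for (i in 1:2) {
    denom <- 0
    for (k in seq_len(m)) denom <- denom + counts[[k]][d[k], i] + eps
    if (denom == 0) {            # no training mass at the observed divisions
      lik[i] <- 0
      next
    }
    prod_cond <- 1
    for (j in seq_len(m)) {
      prod_cond <- prod_cond * (counts[[j]][d[j], i] + eps) / denom
    }
    lik[i] <- prod_cond
  }
  if (lik[1] + lik[2] == 0) return(c(NA_real_, NA_real_))
  lik / (lik[1] + lik[2])
}

# Standard naive-Bayes normalization: each marker's conditional is its count
# over that marker's own (smoothed) division total for the class.
oracle_posterior_per_marker <- function(counts, d, eps) {
  lik <- c(1, 1)
  for (i in 1:2) {
    for (j in seq_along(counts)) {
      denom <- sum(counts[[j]][, i] + eps)
      if (denom == 0) {
        lik[i] <- 0
        break
      }
      lik[i] <- lik[i] * (counts[[j]][d[j], i] + eps) / denom
    }
  }
  if (lik[1] + lik[2] == 0) return(c(NA_real_, NA_real_))
  lik / (lik[1] + lik[2])
}

# Closed-form simple linear regression of y on x.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Textbook pooled-variance two-sample t statistic and two-sided p.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Holm step-down adjustment written from its definition.
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (r in seq_len(n)) {
    running <- max(running, (n - r + 1) * p[o[r]])
    adj[o[r]] <- min(running, 1)
  }
  adj
}

# Build a discrete Bayes model object directly from a list of count
# matrices (division x class), bypassing fit_model, for grid checks.
make_model <- function(counts, eps, conditional = "cross_marker",
                       classes = c("RES", "NRES")) {
  ndiv <- vapply(counts, nrow, integer(1))
  scheme <- lapply(ndiv, function(D) seq_len(D - 1))
  names(scheme) <- names(counts) <- paste0("m", seq_along(counts))
  scheme <- structure(scheme, class = "discretization_scheme",
                      divisions = ndiv)
  counts <- lapply(counts, function(cm) {
    dimnames(cm) <- list(division = seq_len(nrow(cm)), class = classes)
    cm
  })
  structure(list(scheme = scheme, counts = counts, classes = classes,
                 n_class = c(sum(vapply(counts, function(cm) cm[1, 1], numeric(1))),
                             NA),
                 eps = eps, priors = c(0.5, 0.5), conditional = conditional),
            class = "discrete_bayes_model")
}

# Marker matrix fixture: 8 markers, two planted informative ones, NB counts
# normalized by library size on the log2 scale.
recovery_fixture <- function(seed, log2fc = 1.2, n_res = 15, n_nres = 15) {
  sig <- c(M3 = log2fc, M6 = log2fc)
  cfg <- sim_config(n_genes = 8, n_res = n_res, n_nres = n_nres,
                    signature = sig, baseline_mean_range = c(50, 500),
                    seed = seed)
  sim <- simulate_counts(cfg)
  rownames(sim$counts) <- c("M3", "M6", paste0("M", c(1, 2, 4, 5, 7, 8)))
  ls <- colSums(sim$counts)
  x <- t(log2(sweep(sim$counts, 2, ls / mean(ls), "/") + 0.5))
  list(x = x, labels = sim$labels, planted = c("M3", "M6"))
}
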