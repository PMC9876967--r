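#' Default planted expression signature
#'
#' The 19-gene interferon-dominated signature used as the generator's
#' default planted effect: gene ids with their true log2 fold changes
#' (non-responders relative to responders). Positive values mean higher
#' expression in non-responders.
#'
#' @return Named numeric vector of log2 fold changes.
#' @export
default_signature <- function() {
  c(OAS3 = 0.864, ISG15 = 0.923, RSAD2 = 0.905, HERC5 = 0.795,
    IFIT1 = 1.161, SIGLEC1 = 1.178, IFI6 = 0.908, GYPE = -0.6,
    IFI44 = 0.704, IFI44L = 0.997, IFIT3 = 0.799, LRRC2 = 0.707,
    EPHX1 = 0.631, RAP1GAP = 1.959, RPS26 = 1.012, OASL = 0.641,
    ACCS = -0.736, MGC70870 = -0.731, SLC14A1 = 0.696)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the discovery cohort the pipeline is designed for:
#' 15 responders vs 15 non-responders, a few thousand genes of
#' negative-binomial counts with log-normal library-size variation, and the
#' 19-gene planted signature of [default_signature()].
#'
#' @param n_genes total number of simulated genes (including signature genes).
#' @param n_res,n_nres group sizes; each >= 2.
#' @param signature named numeric vector: planted log2 fold change
#'   (NRES over RES) per signature gene. May be empty for a null dataset.
#' @param baseline_mean_range length-2 positive interval; per-gene baseline
#'   means are drawn log-uniformly over it.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2), > 0 and shared by all genes.
#' @param libsize_cv coefficient of variation of the log-normal per-sample
#'   library-size factors, >= 0.
#' @param qpcr_noise_sd Gaussian noise on the Cq scale, in cycles, >= 0.
#' @param seed integer random seed; identical config + seed gives
#'   bit-identical data.
#' @return A validated \code{"sim_config"} list.
#' @export
sim_config <- function(n_genes = 5000L, n_res = 15L, n_nres = 15L,
                       signature = default_signature(),
                       baseline_mean_range = c(5, 500),
                       dispersion = 0.1, libsize_cv = 0.2,
                       qpcr_noise_sd = 0.15, seed = 1L) {
  fail <- function(field, why) stop("invalid '", field, "': ", why)
  if (length(n_genes) != 1 || n_genes < 1 || n_genes != round(n_genes)) {
    fail("n_genes", "must be a positive integer")
  }
  if (n_res < 2) fail("n_res", "need at least 2 responders")
  if (n_nres < 2) fail("n_nres", "need at least 2 non-responders")
  if (length(signature) && is.null(names(signature))) {
    fail("signature", "must be named by gene id")
  }
  if (anyDuplicated(names(signature))) fail("signature", "duplicate gene ids")
  if (length(signature) > n_genes) {
    fail("signature", "more signature genes than n_genes")
  }
  if (length(baseline_mean_range) != 2 || any(baseline_mean_range <= 0) ||
      diff(baseline_mean_range) < 0) {
    fail("baseline_mean_range", "must be a positive increasing interval")
  }
  if (dispersion <= 0) fail("dispersion", "must be > 0")
  if (libsize_cv < 0) fail("libsize_cv", "must be >= 0")
  if (qpcr_noise_sd < 0) fail("qpcr_noise_sd", "must be >= 0")
  structure(list(n_genes = as.integer(n_genes), n_res = as.integer(n_res),
                 n_nres = as.integer(n_nres), signature = signature,
                 baseline_mean_range = baseline_mean_range,
                 dispersion = dispersion, libsize_cv = libsize_cv,
                 qpcr_noise_sd = qpcr_noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(config) {
  sig <- names(config$signature)
  filler <- sprintf("GENE%05d", seq_len(config$n_genes - length(sig)))
  c(sig, filler)
}

sim_sample_ids <- function(config) {
  c(sprintf("RES%02d", seq_len(config$n_res)),
    sprintf("NRES%02d", seq_len(config$n_nres)))
}

#' Simulate a two-group RNA-seq count matrix with a planted signature
#'
#' Gene-wise baseline means are log-uniform over the configured range;
#' counts are negative-binomial with a shared dispersion. Library-size
#' factors are log-normal with the configured CV and multiply every gene
#' mean of a sample. Signature genes have their mean multiplied by
#' \code{2^log2FC} in the non-responder group only; all other genes are
#' identically distributed in both groups.
#'
#' @param config a [sim_config()].
#' @return A list with \code{counts} (integer matrix, genes x samples),
#'   \code{labels} (named character vector, \code{"RES"}/\code{"NRES"}),
#'   and \code{ground_truth} (list: \code{informative_genes},
#'   \code{effects}).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_ids(config)
  samples <- sim_sample_ids(config)
  labels <- stats::setNames(rep(c("RES", "NRES"), c(config$n_res, config$n_nres)),
                            samples)
  n <- length(samples)
  set.seed(config$seed)
  lr <- log(config$baseline_mean_range)
  mu <- exp(stats::runif(config$n_genes, lr[1], lr[2]))
  names(mu) <- genes
  sdlog <- sqrt(log(1 + config$libsize_cv^2))
  sf <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))   # mean-1 log-normal
  effect <- matrix(1, config$n_genes, n, dimnames = list(genes, samples))
  if (length(config$signature)) {
    effect[names(config$signature), labels == "NRES"] <- 2^config$signature
  }
  mean_mat <- mu * effect * rep(sf, each = config$n_genes)
  counts <- matrix(
    stats::rnbinom(length(mean_mat), mu = mean_mat, size = 1 / config$dispersion),
    config$n_genes, n, dimnames = list(genes, samples)
  )
  list(counts = counts, labels = labels,
       ground_truth = list(informative_genes = names(config$signature),
                           effects = config$signature))
}

#' Simulate qPCR plates: dilution series and duplicate sample measurements
#'
#' For every requested gene plus the B2M internal control, a true standard
#' line \code{Cq = intercept + slope * log10(concentration)} is drawn
#' (slope near the perfect-efficiency -3.32 cycles/decade), a 6-point
#' 2-fold dilution series from 10 down to 0.3125 fM is measured, and every
#' sample is measured in duplicate. Sample template concentrations carry
#' the planted signature effect for signature genes; B2M carries none.
#' Measurement noise is Gaussian on the Cq scale with sd
#' \code{config$qpcr_noise_sd}.
#'
#' @param config a [sim_config()].
#' @param genes character vector of gene ids to assay (B2M is added
#'   automatically); unknown ids (absent from the simulated gene universe)
#'   are an error.
#' @return A list with \code{dilution} (data frame: gene, concentration_fM,
#'   cq), \code{plate} (data frame: sample_id, gene, replicate, cq),
#'   \code{labels}, and \code{truth} (per-gene true slope/intercept and the
#'   true sample concentrations).
#' @export
simulate_qpcr_dataset <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(genes)) stop("'genes' must be non-empty")
  universe <- sim_gene_ids(config)
  unknown <- setdiff(genes, universe)
  if (length(unknown)) stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  assay <- c(genes, "B2M")
  samples <- sim_sample_ids(config)
  labels <- stats::setNames(rep(c("RES", "NRES"), c(config$n_res, config$n_nres)),
                            samples)
  dil_conc <- c(10, 5, 2.5, 1.25, 0.625, 0.3125)
  set.seed(config$seed + 1L)
  slope <- -3.321928 + stats::rnorm(length(assay), 0, 0.05)
  intercept <- stats::runif(length(assay), 28, 33)
  names(slope) <- names(intercept) <- assay
  dilution <- do.call(rbind, lapply(assay, function(g) {
    data.frame(gene = g, concentration_fM = dil_conc,
               cq = intercept[g] + slope[g] * log10(dil_conc) +
                 stats::rnorm(length(dil_conc), 0, config$qpcr_noise_sd))
  }))
  # true template concentrations (fM): log-normal around 1 fM, signature
  # effect applied on the linear scale in the NRES group
  conc <- matrix(exp(stats::rnorm(length(samples) * length(assay), 0, 0.25)),
                 length(samples), length(assay),
                 dimnames = list(samples, assay))
  sig <- config$signature[names(config$signature) %in% genes]
  if (length(sig)) {
    conc[labels == "NRES", names(sig)] <-
      conc[labels == "NRES", names(sig), drop = FALSE] *
      rep(2^sig, each = sum(labels == "NRES"))
  }
  plate <- expand.grid(sample_id = samples, gene = assay, replicate = 1:2,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  true_cq <- intercept[plate$gene] +
    slope[plate$gene] * log10(conc[cbind(plate$sample_id, plate$gene)])
  plate$cq <- true_cq + stats::rnorm(nrow(plate), 0, config$qpcr_noise_sd)
  list(dilution = dilution, plate = plate, labels = labels,
       truth = list(slope = slope, intercept = intercept, concentration = conc))
}

#' Simulate pre/post depression severity scores consistent with the labels
#'
#' Pre-treatment SIGH-D scores are drawn around 20 points; responders are
#' given a post score whose improvement is at least 50% of the pre score,
#' non-responders strictly less, so that [label_response()] applied to the
#' scores reproduces the simulated group labels exactly.
#'
#' @param config a [sim_config()].
#' @return A data frame with columns \code{sample_id}, \code{pre},
#'   \code{post}, \code{label}.
#' @export
simulate_sighd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sim_sample_ids(config)
  labels <- rep(c("RES", "NRES"), c(config$n_res, config$n_nres))
  set.seed(config$seed + 2L)
  pre <- pmax(10L, round(stats::rnorm(length(samples), 20, 4)))
  improvement <- ifelse(labels == "RES",
                        stats::runif(length(samples), 0.5, 0.95),
                        stats::runif(length(samples), 0.0, 0.45))
  # floor keeps responders at >= the drawn improvement; ceiling keeps
  # non-responders below theirs (both stay on integer score points)
  post <- ifelse(labels == "RES",
                 floor(pre * (1 - improvement)),
                 ceiling(pre * (1 - improvement)))
  data.frame(sample_id = samples, pre = as.integer(pre),
             post = as.integer(post), label = labels,
             stringsAsFactors = FALSE)
}
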