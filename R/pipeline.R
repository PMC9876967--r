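#' Label treatment response from pre/post severity scores
#'
#' A participant whose SIGH-D score improves by at least 50% of the
#' pre-treatment score is a responder (\code{"RES"}); anything less is a
#' non-responder (\code{"NRES"}). The 50% boundary is inclusive.
#'
#' @param pre positive pre-treatment score(s).
#' @param post post-treatment score(s), same length.
#' @return Character vector of \code{"RES"}/\code{"NRES"} labels.
#' @examples
#' label_response(20, 10)  # exactly 50% improvement -> "RES"
#' @export
label_response <- function(pre, post) {
  if (any(pre <= 0)) stop("pre-treatment score must be > 0 for labeling")
  ifelse((pre - post) / pre >= 0.5, "RES", "NRES")
}

## ---- TSV / JSON interchange ------------------------------------------------

#' Read / write a gene x sample expression matrix as TSV
#'
#' The dialect is tab-separated UTF-8 with a mandatory header row of sample
#' ids and gene ids in the first column. Duplicate gene or sample ids and
#' non-numeric cells are rejected with the offending id or line.
#'
#' @param path file path.
#' @return \code{read_matrix}: a numeric matrix, genes x samples.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix TSV needs a gene column plus sample columns")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1])
  sdup <- colnames(df)[-1][duplicated(colnames(df)[-1])]
  if (length(sdup)) stop("duplicate sample id: ", sdup[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 1,
                                              function(r) sum(as.numeric(r))))))[1]
    stop("non-numeric cell at data line ", bad)
  }
  rownames(m) <- ids
  m
}

#' @param m numeric matrix, genes x samples.
#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample labels as two-column TSV
#'
#' Columns \code{sample_id} and \code{label} (\code{RES}/\code{NRES}).
#' @param path file path.
#' @return \code{read_labels}: named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df))) {
    stop("labels TSV needs columns sample_id, label")
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id: ", dup[1])
  bad <- setdiff(unique(df$label), c("RES", "NRES"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$label, df$sample_id)
}

#' @param labels named character vector of labels.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Serialize / restore a discrete Bayes model as JSON
#'
#' Round-trips the discretization cut points, division counts, class
#' labels, smoothing constant and conditional-normalization mode, so a
#' restored model reproduces every posterior bit for bit.
#'
#' @param model a \code{"discrete_bayes_model"}.
#' @param path file path.
#' @return \code{read_model}: the restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "discrete_bayes_model"))
  payload <- list(
    scheme = lapply(model$scheme, identity),
    divisions = as.integer(attr(model$scheme, "divisions")),
    counts = lapply(model$counts, function(m) {
      list(dim = dim(m), values = as.vector(m))
    }),
    classes = model$classes,
    n_class = model$n_class,
    eps = model$eps,
    conditional = model$conditional
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  scheme <- lapply(p$scheme, as.numeric)
  scheme <- structure(scheme, class = "discretization_scheme",
                      divisions = as.integer(p$divisions))
  counts <- lapply(p$counts, function(cm) {
    matrix(as.integer(cm$values), cm$dim[1], cm$dim[2],
           dimnames = list(division = seq_len(cm$dim[1]), class = p$classes))
  })
  names(counts) <- names(scheme)
  structure(
    list(scheme = scheme, counts = counts, classes = p$classes,
         n_class = as.integer(p$n_class), eps = p$eps, priors = c(0.5, 0.5),
         conditional = p$conditional),
    class = "discrete_bayes_model"
  )
}

## ---- Test-set firewall -----------------------------------------------------

#' Seal labels behind an access-logging accessor
#'
#' The pipeline keeps test-set labels inside a sealed container; every read
#' must go through [unseal()], which records the stage name. The run report
#' exposes the log, so an audit can verify that nothing before the final
#' evaluation stage ever touched test labels.
#'
#' @param labels named character label vector.
#' @return A \code{"sealed_labels"} environment.
#' @export
seal_labels <- function(labels) {
  env <- new.env(parent = emptyenv())
  env$labels <- labels
  env$log <- character(0)
  class(env) <- "sealed_labels"
  env
}

#' @param sealed a \code{"sealed_labels"} container.
#' @param stage character stage name recorded in the access log.
#' @rdname seal_labels
#' @export
unseal <- function(sealed, stage) {
  stopifnot(inherits(sealed, "sealed_labels"))
  sealed$log <- c(sealed$log, stage)
  sealed$labels
}

#' @rdname seal_labels
#' @export
access_log <- function(sealed) sealed$log

## ---- End-to-end pipeline ---------------------------------------------------

#' Pipeline configuration
#'
#' Collects and validates every stage parameter of [run_pipeline()]. Pass a
#' YAML file path to load a flat-key configuration from disk (requires the
#' \pkg{yaml} package).
#'
#' @param train,test \code{"sim_config"} objects for the training and test
#'   cohorts (defaults: 15/15 and 22/12 with the default signature); used
#'   when data are simulated.
#' @param p_threshold,fc_threshold,min_mean_count,top_n screening settings,
#'   see [select_validation_targets()].
#' @param max_markers candidate-panel cap for marker selection (default 8).
#' @param k combination size, 2 or 3.
#' @param criterion a [selection_criterion()].
#' @param divisions,eps,conditional classifier settings, see [fit_model()].
#' @param seed integer master seed.
#' @return A validated \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(train = sim_config(n_res = 15, n_nres = 15, seed = seed),
                            test = sim_config(n_res = 22, n_nres = 12, seed = seed + 1L),
                            p_threshold = 0.01, fc_threshold = 1.5,
                            min_mean_count = 50, top_n = 10,
                            max_markers = 8L, k = 2L,
                            criterion = selection_criterion("sensitivity"),
                            divisions = 2L, eps = 0.5,
                            conditional = "cross_marker", seed = 1L) {
  seed <- as.integer(seed)
  force(train); force(test)
  stopifnot(inherits(train, "sim_config"), inherits(test, "sim_config"),
            inherits(criterion, "selection_criterion"))
  if (!k %in% 2:3) stop("'k' must be 2 or 3")
  if (p_threshold <= 0 || fc_threshold <= 0) stop("thresholds must be > 0")
  structure(list(train = train, test = test, p_threshold = p_threshold,
                 fc_threshold = fc_threshold, min_mean_count = min_mean_count,
                 top_n = top_n, max_markers = as.integer(max_markers),
                 k = as.integer(k), criterion = criterion,
                 divisions = divisions, eps = eps, conditional = conditional,
                 seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [pipeline_config()]; simulation
#' sub-configs are nested maps under \code{train}/\code{test}.
#' @param path YAML file path.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  mk_sim <- function(lst, default_seed) {
    if (is.null(lst)) return(NULL)
    lst$signature <- if (!is.null(lst$signature)) unlist(lst$signature) else default_signature()
    if (is.null(lst$seed)) lst$seed <- default_seed
    do.call(sim_config, lst)
  }
  args <- list(
    p_threshold = y$p_threshold %||% 0.01,
    fc_threshold = y$fc_threshold %||% 1.5,
    min_mean_count = y$min_mean_count %||% 50,
    top_n = y$top_n %||% 10,
    max_markers = y$max_markers %||% 8L,
    k = y$k %||% 2L,
    criterion = selection_criterion(y$criterion %||% "sensitivity",
                                    y$specificity_floor %||% 0.5),
    divisions = y$divisions %||% 2L,
    eps = y$eps %||% 0.5,
    conditional = y$conditional %||% "cross_marker",
    seed = seed
  )
  tr <- mk_sim(y$train, seed)
  te <- mk_sim(y$test, seed + 1L)
  if (!is.null(tr)) args$train <- tr
  if (!is.null(te)) args$test <- te
  do.call(pipeline_config, args)
}

#' Run the marker-discovery pipeline end to end
#'
#' Simulates (or accepts) a training and a test cohort, screens the
#' training counts (TMM + NB likelihood-ratio test), picks qPCR validation
#' targets, restricts to a candidate marker panel, selects the best
#' \code{k}-marker combination by leave-one-out frequency voting on the
#' training set only, fits the final discrete Bayes model on all training
#' samples, classifies the held-out test samples, and reports training
#' (re-substitution) and test performance. Test labels live in a sealed
#' container whose access log is part of the report, so the test-set
#' firewall is auditable.
#'
#' @param config a [pipeline_config()].
#' @param train_data,test_data optional lists with \code{counts} and
#'   \code{labels} (as produced by [simulate_counts()]); when omitted the
#'   configured cohorts are simulated.
#' @return A \code{"pipeline_report"} list: parameters, screening table,
#'   validation targets, candidate panel, selection result, final model,
#'   training and test metrics, predictions, and the firewall access log.
#' @export
run_pipeline <- function(config, train_data = NULL, test_data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(train_data)) train_data <- simulate_counts(config$train)
  if (is.null(test_data)) test_data <- simulate_counts(config$test)
  sealed_test <- seal_labels(test_data$labels)
  test_counts <- test_data$counts

  ## screen (training only)
  factors <- compute_tmm_factors(train_data$counts)
  de <- de_test(train_data$counts, train_data$labels, factors,
                config$p_threshold, config$fc_threshold)
  targets <- select_validation_targets(de, config$p_threshold,
                                       config$fc_threshold,
                                       config$min_mean_count, config$top_n)
  if (length(targets) < config$k) {
    stop("stage 'screen': only ", length(targets),
         " validation targets; cannot select ", config$k, "-marker combinations")
  }
  panel <- utils::head(targets, config$max_markers)

  ## marker values: TMM-normalized log2 expression of the panel genes
  marker_values <- function(counts, f) {
    z <- sweep(counts[panel, , drop = FALSE], 2, as.numeric(f), "/")
    t(log2(z + 0.5))
  }
  x_train <- marker_values(train_data$counts, factors)

  ## leave-one-out selection on training samples only
  sel <- loo_select(x_train, train_data$labels, k = config$k,
                    criterion = config$criterion, divisions = config$divisions,
                    eps = config$eps, conditional = config$conditional)

  ## final model on all training samples, winning combination
  xw <- x_train[, sel$winner, drop = FALSE]
  scheme <- fit_discretization(xw, config$divisions)
  model <- fit_model(discretize(scheme, xw), train_data$labels, scheme,
                     eps = config$eps, conditional = config$conditional)
  train_pred <- classify(model, discretize(scheme, xw))
  train_cm <- confusion(stats::setNames(train_pred$label, rownames(xw)),
                        train_data$labels)

  ## classify the held-out test set (labels still sealed)
  test_factors <- compute_tmm_factors(test_counts)
  x_test <- marker_values(test_counts, test_factors)[, sel$winner, drop = FALSE]
  test_pred <- classify(model, discretize(scheme, x_test))

  ## evaluation is the only stage that unseals test labels
  test_labels <- unseal(sealed_test, "evaluate")
  test_cm <- confusion(stats::setNames(test_pred$label, rownames(x_test)),
                       test_labels)

  structure(
    list(config = config,
         de_results = de,
         validation_targets = targets,
         panel = panel,
         selection = sel,
         model = model,
         train_metrics = compute_metrics(train_cm),
         test_metrics = compute_metrics(test_cm),
         train_predictions = train_pred,
         test_predictions = test_pred,
         firewall_log = access_log(sealed_test)),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Marker-discovery pipeline report\n")
  cat("validation targets:", paste(x$validation_targets, collapse = ", "), "\n")
  cat("winning combination:", paste(x$selection$winner, collapse = " + "), "\n")
  cat("training (re-substitution):\n")
  print(x$train_metrics)
  cat("test:\n")
  print(x$test_metrics)
  cat("test-label accesses:", paste(x$firewall_log, collapse = ", "), "\n")
  invisible(x)
}
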