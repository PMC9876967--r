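#' Enumerate marker combinations
#'
#' All size-\code{k} subsets of the candidate markers, each sorted
#' internally, in lexicographic order.
#'
#' @param markers character vector of distinct marker ids.
#' @param k combination size (k <= length(markers)).
#' @return A list of sorted character vectors of length \code{k}.
#' @examples
#' length(enumerate_combinations(paste0("g", 1:8), 2))  # 28
#' @export
enumerate_combinations <- function(markers, k) {
  if (anyDuplicated(markers)) stop("marker ids must be distinct")
  if (k > length(markers)) {
    stop("cannot choose ", k, " markers from ", length(markers))
  }
  combs <- utils::combn(sort(markers), k, simplify = FALSE)
  combs
}

#' Selection criterion for per-fold combination choice
#'
#' @param mode \code{"sensitivity"}: maximal sensitivity subject to a
#'   specificity floor (falling back to maximal specificity, flagged, if no
#'   candidate meets the floor); or \code{"f1"}: maximal F1 measure. Ties
#'   are broken by higher accuracy, then lexicographically by combination.
#' @param specificity_floor floor in [0, 1] used by the sensitivity mode;
#'   default 0.5.
#' @return A \code{"selection_criterion"} object.
#' @export
selection_criterion <- function(mode = c("sensitivity", "f1"),
                                specificity_floor = 0.5) {
  mode <- match.arg(mode)
  if (specificity_floor < 0 || specificity_floor > 1) {
    stop("'specificity_floor' must lie in [0, 1]")
  }
  structure(list(mode = mode, specificity_floor = specificity_floor),
            class = "selection_criterion")
}

#' Re-substitution performance of one marker combination
#'
#' Fits the discretization and the discrete Bayes model on the given
#' samples restricted to the combination's markers, then reclassifies the
#' *same* samples and scores the resulting confusion matrix. This is the
#' re-substitution estimate used to rank candidate combinations inside each
#' leave-one-out fold.
#'
#' @param x numeric matrix of marker values (samples x markers); row names
#'   are sample ids.
#' @param labels character class labels per row of \code{x}.
#' @param combination character vector of marker ids (columns of \code{x}).
#' @param divisions,eps,conditional classifier settings, see [fit_model()].
#' @return A \code{"classification_metrics"} object.
#' @export
resubstitution_metrics <- function(x, labels, combination, divisions = 2L,
                                   eps = 0.5, conditional = "cross_marker") {
  x <- as.matrix(x)
  if (!all(combination %in% colnames(x))) stop("unknown marker in combination")
  xs <- x[, combination, drop = FALSE]
  scheme <- fit_discretization(xs, divisions)
  d <- discretize(scheme, xs)
  model <- fit_model(d, labels, scheme, eps = eps, conditional = conditional)
  pred <- classify(model, d)
  names(labels) <- rownames(d) %||% paste0("s", seq_along(labels))
  cm <- confusion(stats::setNames(pred$label, names(labels)), labels)
  compute_metrics(cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pick the best candidate given a list of metrics, per the criterion.
# Returns list(index, fallback) where fallback marks the degenerate case in
# which no candidate met the specificity floor.
select_best_candidate <- function(metrics_list, combs, criterion) {
  acc <- vapply(metrics_list, `[[`, numeric(1), "accuracy")
  key <- vapply(combs, paste, character(1), collapse = "+")
  fallback <- FALSE
  if (criterion$mode == "sensitivity") {
    spec <- vapply(metrics_list, `[[`, numeric(1), "specificity")
    sens <- vapply(metrics_list, `[[`, numeric(1), "sensitivity")
    ok <- spec >= criterion$specificity_floor
    if (any(ok)) {
      score <- ifelse(ok, sens, -Inf)
    } else {
      score <- spec
      fallback <- TRUE
    }
  } else {
    score <- vapply(metrics_list, `[[`, numeric(1), "f1")
  }
  ord <- order(-score, -acc, key)
  list(index = ord[1], fallback = fallback)
}

#' Select the best marker combination inside one fold
#'
#' Evaluates every candidate combination by re-substitution on the
#' sub-training samples and applies the selection criterion. The left-out
#' sub-test sample plays no part.
#'
#' @param x numeric matrix of sub-training marker values (samples x markers).
#' @param labels sub-training class labels.
#' @param candidates list of combinations from [enumerate_combinations()].
#' @param criterion a \code{"selection_criterion"}.
#' @inheritParams resubstitution_metrics
#' @return A list with \code{combination}, its \code{metrics}, and
#'   \code{fallback} (TRUE when the specificity floor was unattainable).
#' @export
select_per_fold <- function(x, labels, candidates, criterion,
                            divisions = 2L, eps = 0.5,
                            conditional = "cross_marker") {
  if (!length(candidates)) stop("no candidate combinations supplied")
  metrics_list <- lapply(candidates, function(cc) {
    resubstitution_metrics(x, labels, cc, divisions, eps, conditional)
  })
  best <- select_best_candidate(metrics_list, candidates, criterion)
  list(combination = candidates[[best$index]],
       metrics = metrics_list[[best$index]],
       fallback = best$fallback)
}

#' Leave-one-out marker-combination selection with frequency voting
#'
#' Each training sample is left out once; on the remaining sub-training
#' samples every size-\code{k} combination of the candidate markers is
#' scored by re-substitution and one combination is selected per fold by
#' the criterion. The combination selected most often across folds is the
#' winner. Discretization and model fitting are redone from scratch inside
#' every fold, so no information about the left-out sample leaks into the
#' choice.
#'
#' Fold-level ties in the criterion are broken by higher accuracy, then
#' lexicographically; a frequency tie between combinations is broken by the
#' better mean re-substitution F1 across the folds that chose them, then
#' lexicographically, so the result is deterministic and invariant to
#' sample order.
#'
#' @param x numeric matrix of training marker values (samples x markers),
#'   rows named by sample id.
#' @param labels character class labels per row.
#' @param k combination size, 2 or 3.
#' @param criterion a \code{"selection_criterion"}.
#' @inheritParams resubstitution_metrics
#' @return An object of class \code{"selection_result"}: winner, frequency
#'   table, per-fold selections, criterion, and the total number of
#'   candidate evaluations performed.
#' @export
loo_select <- function(x, labels, k = 2L,
                       criterion = selection_criterion("sensitivity"),
                       divisions = 2L, eps = 0.5,
                       conditional = "cross_marker") {
  x <- as.matrix(x)
  if (!k %in% c(2L, 3L)) stop("'k' must be 2 or 3")
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (nrow(x) != length(labels)) stop("one label per training sample required")
  cls <- table(labels)
  if (length(cls) != 2 || any(cls < 3)) {
    stop("need two classes with at least 3 training samples each")
  }
  candidates <- enumerate_combinations(colnames(x), k)
  n <- nrow(x)
  folds <- vector("list", n)
  n_eval <- 0L
  for (i in seq_len(n)) {
    sub_x <- x[-i, , drop = FALSE]
    sub_lab <- labels[-i]
    sel <- select_per_fold(sub_x, sub_lab, candidates, criterion,
                           divisions, eps, conditional)
    n_eval <- n_eval + length(candidates)
    folds[[i]] <- list(left_out = rownames(x)[i],
                       combination = sel$combination,
                       metrics = sel$metrics,
                       fallback = sel$fallback)
  }
  keys <- vapply(folds, function(f) paste(f$combination, collapse = "+"),
                 character(1))
  freq <- sort(table(keys), decreasing = TRUE)
  top <- names(freq)[freq == max(freq)]
  if (length(top) > 1) {
    mean_f1 <- vapply(top, function(kk) {
      mean(vapply(folds[keys == kk], function(f) f$metrics$f1, numeric(1)))
    }, numeric(1))
    top <- top[order(-mean_f1, top)]
  }
  winner <- strsplit(top[1], "+", fixed = TRUE)[[1]]
  structure(
    list(winner = winner,
         frequency = freq,
         folds = folds,
         criterion = criterion,
         k = k,
         n_evaluations = n_eval,
         tie = length(names(freq)[freq == max(freq)]) > 1),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Leave-one-out marker selection (k = ", x$k, ", criterion: ",
      x$criterion$mode, ")\n", sep = "")
  cat("winner:", paste(x$winner, collapse = " + "),
      if (x$tie) "(frequency tie, broken by mean re-substitution F1)" else "",
      "\n")
  cat("fold votes:\n")
  print(x$frequency)
  invisible(x)
}
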