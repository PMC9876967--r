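test_that("combination enumeration is exhaustive, sorted, and validated", {
  g8 <- paste0("g", 1:8)
  c2 <- enumerate_combinations(g8, 2)
  expect_length(c2, 28)
  expect_length(enumerate_combinations(g8, 3), 56)
  expect_length(enumerate_combinations(c("a", "b", "c"), 3), 1)
  expect_true(all(vapply(c2, function(x) !is.unsorted(x), logical(1))))
  expect_false(anyDuplicated(vapply(c2, paste, character(1), collapse = "+")) > 0)
  expect_error(enumerate_combinations(c("a", "b"), 3), "cannot choose")
  expect_error(enumerate_combinations(c("a", "a", "b"), 2), "distinct")
})

test_that("re-substitution metrics: separable pair is perfect, hand case matches tally", {
  # all responders low in both markers, all non-responders high
  x <- cbind(a = c(1, 2, 3, 11, 12, 13), b = c(5, 6, 7, 50, 60, 70))
  lab <- rep(c("RES", "NRES"), each = 3)
  m <- resubstitution_metrics(x, lab, c("a", "b"), eps = 0)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)

  # hand-constructed 6-sample case, single informative marker + constant-ish
  # noise: divisions of 'a' split 1,2,3 | 4,5,6 at the median 3.5
  x2 <- cbind(a = c(1, 2, 4, 3, 5, 6), b = c(1, 2, 3, 4, 5, 6))
  lab2 <- c("RES", "RES", "RES", "NRES", "NRES", "NRES")
  # divisions a: RES -> 1,1,2 ; NRES -> 1,2,2 ; b: RES -> 1,1,1 ; NRES -> 2,2,2
  # with eps = 0, b separates the classes alone, so predictions follow b:
  # tally is tp 3, fn 0, fp 0, tn 3
  m2 <- resubstitution_metrics(x2, lab2, c("a", "b"), eps = 0)
  expect_equal(m2$accuracy, 1)

  expect_error(resubstitution_metrics(x2, lab2, c("a", "zzz")), "unknown marker")
})

test_that("re-substitution accuracy on permuted labels shows only in-sample optimism", {
  # with uninformative markers the population accuracy is 0.5; the
  # re-substitution estimate sits somewhat above it by construction
  set.seed(5)
  acc <- replicate(60, {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    lab <- sample(rep(c("RES", "NRES"), each = 10))
    resubstitution_metrics(x, lab, c("a", "b"))$accuracy
  })
  expect_gt(mean(acc), 0.45)
  expect_lt(mean(acc), 0.75)
})

test_that("per-fold selection applies the stated criterion and tie-breaks", {
  mk <- function(sens, spec, f1, acc) {
    list(sensitivity = sens, specificity = spec, f1 = f1, accuracy = acc)
  }
  combs <- list(c("A1", "A2"), c("B1", "B2"), c("C1", "C2"))
  # sensitivity mode with floor 0.5: A fails the floor, B beats C on sensitivity
  ms <- list(mk(0.9, 0.4, 0.6, 0.6), mk(0.8, 0.6, 0.7, 0.7), mk(0.7, 0.9, 0.75, 0.8))
  sel <- respmarker:::select_best_candidate(ms, combs, selection_criterion("sensitivity"))
  expect_equal(sel$index, 2L)
  expect_false(sel$fallback)

  # nobody meets the floor: fall back to maximal specificity, flagged
  ms2 <- list(mk(0.9, 0.2, 0.6, 0.6), mk(0.8, 0.45, 0.7, 0.7), mk(0.7, 0.3, 0.75, 0.8))
  sel2 <- respmarker:::select_best_candidate(ms2, combs, selection_criterion("sensitivity"))
  expect_equal(sel2$index, 2L)
  expect_true(sel2$fallback)

  # F1 mode with an F1 tie resolved by accuracy
  ms3 <- list(mk(0.7, 0.7, 0.70, 0.70), mk(0.8, 0.8, 0.85, 0.80), mk(0.8, 0.8, 0.85, 0.85))
  sel3 <- respmarker:::select_best_candidate(ms3, combs, selection_criterion("f1"))
  expect_equal(sel3$index, 3L)

  # full tie falls through to the lexicographically first combination
  ms4 <- list(mk(0.8, 0.8, 0.85, 0.85), mk(0.8, 0.8, 0.85, 0.85), mk(0.8, 0.8, 0.85, 0.85))
  sel4 <- respmarker:::select_best_candidate(ms4, combs, selection_criterion("f1"))
  expect_equal(sel4$index, 1L)

  # single candidate is returned as-is through the public surface
  x <- cbind(a = c(1, 2, 3, 11, 12, 13), b = c(5, 6, 7, 50, 60, 70))
  lab <- rep(c("RES", "NRES"), each = 3)
  one <- select_per_fold(x, lab, list(c("a", "b")), selection_criterion("f1"))
  expect_equal(one$combination, c("a", "b"))
})

test_that("leave-one-out voting: one vote per fold, exhaustive evaluation, determinism", {
  fx <- recovery_fixture(seed = 2024)
  sel <- loo_select(fx$x, fx$labels, k = 2,
                    criterion = selection_criterion("f1"),
                    divisions = 3, conditional = "per_marker")
  n <- nrow(fx$x)
  expect_equal(sum(sel$frequency), n)                 # one vote per fold
  expect_length(sel$folds, n)
  expect_equal(sel$n_evaluations, n * choose(8, 2))   # every candidate, every fold
  expect_true(max(sel$frequency) == sel$frequency[paste(sort(sel$winner), collapse = "+")])

  # permuting the training-sample order changes nothing
  perm <- sample(n)
  sel2 <- loo_select(fx$x[perm, ], fx$labels[perm], k = 2,
                     criterion = selection_criterion("f1"),
                     divisions = 3, conditional = "per_marker")
  expect_equal(sort(sel2$winner), sort(sel$winner))
  expect_equal(sel2$frequency[order(names(sel2$frequency))],
               sel$frequency[order(names(sel$frequency))])

  expect_error(loo_select(fx$x, fx$labels, k = 4), "must be 2 or 3")
})

test_that("a dominant pair sweeps every fold", {
  # two perfectly separating markers among noise: every fold must vote for them
  set.seed(77)
  x <- cbind(good1 = c(rnorm(10, 0), rnorm(10, 10)),
             good2 = c(rnorm(10, 0), rnorm(10, 10)),
             noise1 = rnorm(20), noise2 = rnorm(20))
  lab <- rep(c("RES", "NRES"), each = 10)
  sel <- loo_select(x, lab, k = 2, criterion = selection_criterion("f1"),
                    conditional = "per_marker")
  expect_equal(sort(sel$winner), c("good1", "good2"))
  expect_equal(unname(sel$frequency["good1+good2"]), 20)
})

test_that("planted informative pairs are recovered far above the chance level", {
  # 8 candidates give 28 pairs, so chance recovery is ~3.6%; the measured
  # recovery of the procedure under these conditions is around 50-60%
  wins <- 0
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    fx <- recovery_fixture(seed = 3000 + s)
    sel <- loo_select(fx$x, fx$labels, k = 2,
                      criterion = selection_criterion("f1"),
                      divisions = 3, conditional = "per_marker")
    if (setequal(sel$winner, fx$planted)) wins <- wins + 1
  }
  expect_gt(wins / n_seeds, 0.25)
})

test_that("k = 3 selection runs the identical loop over triples", {
  set.seed(99)
  x <- cbind(a = c(rnorm(8, 0), rnorm(8, 6)),
             b = c(rnorm(8, 0), rnorm(8, 6)),
             c = c(rnorm(8, 0), rnorm(8, 6)),
             d = rnorm(16))
  lab <- rep(c("RES", "NRES"), each = 8)
  sel <- loo_select(x, lab, k = 3, criterion = selection_criterion("f1"),
                    conditional = "per_marker")
  expect_equal(sel$n_evaluations, 16 * choose(4, 3))
  expect_length(sel$winner, 3)
  expect_equal(sort(sel$winner), c("a", "b", "c"))
})
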