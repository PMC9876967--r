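test_that("quantile discretization places cuts and assigns divisions as expected", {
  sch <- fit_discretization(cbind(m1 = c(1, 2, 3, 4)), divisions = 2)
  expect_equal(sch$m1, 2.5)
  d <- discretize(sch, cbind(m1 = c(1, 2, 3, 4)))
  expect_equal(as.integer(d), c(1L, 1L, 2L, 2L))

  # a value exactly at a cut goes to the lower division
  expect_equal(as.integer(discretize(sch, cbind(m1 = 2.5))), 1L)
  # values beyond the training range land in the end divisions
  expect_equal(as.integer(discretize(sch, cbind(m1 = c(-100, 100)))), c(1L, 2L))

  sch3 <- fit_discretization(cbind(a = 1:9), divisions = 3)
  expect_equal(as.integer(discretize(sch3, cbind(a = c(1, 4, 9)))), c(1L, 2L, 3L))

  expect_error(fit_discretization(cbind(m1 = rep(1, 5)), 2), "distinct")
  expect_error(fit_discretization(cbind(m1 = c(1, 2)), 3), "distinct")
})

test_that("discretization is invariant to strictly monotone transforms", {
  set.seed(7)
  for (rep in 1:20) {
    x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    div <- sample(2:4, 3, replace = TRUE)
    d1 <- discretize(fit_discretization(x, div), x)
    tx <- exp(x)  # strictly monotone
    d2 <- discretize(fit_discretization(tx, div), tx)
    expect_identical(d1, d2)
  }
})

test_that("fit_model tallies counts and conserves class totals", {
  d <- rbind(c(1L, 2L), c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 1L))
  colnames(d) <- c("A", "B")
  lab <- c("RES", "RES", "RES", "NRES", "NRES")
  sch <- structure(list(A = 0, B = 0), class = "discretization_scheme",
                   divisions = c(2L, 2L))
  m <- fit_model(d, lab, sch, eps = 0)
  expect_equal(unname(m$counts$A[, "RES"]), c(3, 0))
  expect_equal(unname(m$counts$A[, "NRES"]), c(0, 2))
  expect_equal(unname(m$counts$B[, "RES"]), c(1, 2))
  # column sums equal class sample counts for every marker
  for (j in seq_along(m$counts)) {
    expect_equal(unname(colSums(m$counts[[j]])), c(3, 2))
  }
  # permuting training order leaves the model unchanged
  perm <- c(4, 2, 5, 1, 3)
  m2 <- fit_model(d[perm, ], lab[perm], sch, eps = 0)
  expect_equal(m2$counts, m$counts)

  expect_error(fit_model(d, rep("RES", 5), sch), "absent")
})

test_that("posterior reproduces the worked two-marker example", {
  # observed divisions hold 4 and 4 responders, 1 and 3 non-responders:
  # responders (1/2)(1/2) = 1/4, non-responders (1/4)(3/4) = 3/16,
  # posterior for responders (1/4)/(1/4 + 3/16) = 4/7
  counts <- list(matrix(c(4, 0, 1, 0), 2, 2), matrix(c(4, 0, 3, 0), 2, 2))
  model <- make_model(counts, eps = 0)
  p <- posterior(model, c(1L, 1L))
  expect_equal(unname(p), c(4 / 7, 3 / 7))
  expect_equal(sum(p), 1)
  cl <- classify(model, c(1L, 1L))
  expect_equal(cl$label, "RES")
  expect_false(cl$tie)
})

test_that("posterior edge cases: zero likelihood, symmetry, ties", {
  # divisions never seen in one class give that class posterior 0
  counts <- list(matrix(c(3, 0, 0, 3), 2, 2), matrix(c(2, 1, 0, 3), 2, 2))
  model <- make_model(counts, eps = 0)
  expect_equal(unname(posterior(model, c(1L, 1L))), c(1, 0))
  expect_equal(classify(model, c(2L, 2L))$label, "NRES")

  # identical counts for both classes give an exact tie, resolved to RES
  counts_eq <- list(matrix(c(2, 1, 2, 1), 2, 2), matrix(c(1, 2, 1, 2), 2, 2))
  meq <- make_model(counts_eq, eps = 0)
  expect_equal(unname(posterior(meq, c(1L, 2L))), c(0.5, 0.5))
  cl <- classify(meq, c(1L, 2L))
  expect_equal(cl$label, "RES")
  expect_true(cl$tie)

  # all relevant counts zero without smoothing is an error pointing at eps
  counts0 <- list(matrix(c(0, 2, 0, 2), 2, 2), matrix(c(0, 2, 0, 2), 2, 2))
  m0 <- make_model(counts0, eps = 0)
  expect_error(posterior(m0, c(1L, 1L)), "eps")
  # with smoothing the same sample has a well-defined posterior
  expect_equal(sum(posterior(make_model(counts0, eps = 0.5), c(1L, 1L))), 1)
})

test_that("posterior matches the literal formula transcription on small count tables", {
  set.seed(11)
  checked <- 0
  # exhaustive over 2 markers x 2 divisions with counts 0..2
  grid <- expand.grid(a1 = 0:2, a2 = 0:2, b1 = 0:2, b2 = 0:2)
  for (r in seq_len(nrow(grid))) {
    g <- as.numeric(grid[r, ])
    counts <- list(matrix(c(g[1], 2 - g[1], g[2], 2 - g[2]), 2, 2),
                   matrix(c(g[3], 2 - g[3], g[4], 2 - g[4]), 2, 2))
    for (eps in c(0, 0.5)) {
      model <- make_model(counts, eps = eps)
      d <- c(1L, 1L)
      want <- oracle_posterior_cross(counts, d, eps)
      if (anyNA(want)) {
        expect_error(posterior(model, d), "eps")
      } else {
        expect_equal(unname(posterior(model, d)), want, tolerance = 1e-12)
        checked <- checked + 1
      }
    }
  }
  # random tables up to 3 markers x 3 divisions, counts <= 5, random sample
  for (rep in 1:800) {
    m <- sample(1:3, 1)
    counts <- lapply(seq_len(m), function(j) {
      D <- sample(2:3, 1)
      matrix(sample(0:5, 2 * D, replace = TRUE), D, 2)
    })
    d <- vapply(counts, function(cm) sample(seq_len(nrow(cm)), 1), integer(1))
    eps <- sample(c(0, 0.5, 1), 1)
    model <- make_model(counts, eps = eps)
    want <- oracle_posterior_cross(counts, d, eps)
    if (anyNA(want)) next
    expect_equal(unname(posterior(model, d)), want, tolerance = 1e-12)
    # and the per-marker switch against its own oracle
    model2 <- make_model(counts, eps = eps, conditional = "per_marker")
    want2 <- oracle_posterior_per_marker(counts, d, eps)
    if (!anyNA(want2)) {
      expect_equal(unname(posterior(model2, d)), want2, tolerance = 1e-12)
    }
    checked <- checked + 1
  }
  expect_gt(checked, 500)
})

test_that("single-marker behavior matches each normalization's closed form", {
  set.seed(3)
  for (rep in 1:50) {
    D <- sample(2:4, 1)
    cm <- matrix(sample(0:6, 2 * D, replace = TRUE), D, 2)
    # under the cross-marker denominator a single marker's conditional is
    # (n + eps)/(n + eps) = 1 for both classes, so the posterior is uniform
    model <- make_model(list(cm), eps = 0.5)
    for (d in seq_len(D)) {
      expect_equal(unname(posterior(model, d)), c(0.5, 0.5))
    }
    # under per-marker normalization with equal class totals the rule
    # reduces to comparing the division counts of the two classes
    cm_bal <- cbind(cm[, 1], cm[sample(D), 1])
    model2 <- make_model(list(cm_bal), eps = 0.5, conditional = "per_marker")
    for (d in seq_len(D)) {
      p <- posterior(model2, d)
      if (cm_bal[d, 1] == cm_bal[d, 2]) {
        expect_equal(unname(p), c(0.5, 0.5))
      } else {
        expect_equal(p[1] > p[2], cm_bal[d, 1] > cm_bal[d, 2],
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("classification is invariant to monotone transforms of the raw values", {
  set.seed(21)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), c("a", "b")))
  lab <- rep(c("RES", "NRES"), each = 10)
  sch <- fit_discretization(x, 2)
  mod <- fit_model(discretize(sch, x), lab, sch)
  pred1 <- classify(mod, discretize(sch, x))$label

  tx <- 1 - exp(-x)  # strictly increasing
  sch2 <- fit_discretization(tx, 2)
  mod2 <- fit_model(discretize(sch2, tx), lab, sch2)
  expect_identical(classify(mod2, discretize(sch2, tx))$label, pred1)
})
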