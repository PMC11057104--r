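test_that("ABD and rABD match hand-worked arithmetic", {
  truth <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s1", c("a", "b")))
  cand <- matrix(c(0.6, 0.4), 1, 2, dimnames = dimnames(truth))
  base <- matrix(c(0.8, 0.2), 1, 2, dimnames = dimnames(truth))
  expect_equal(abd(cand, base, truth), 0.2 - 0.6)
  expect_equal(as.numeric(rabd(cand, base, truth)), 20 - 60)
})

test_that("perfect candidate and identical estimates behave as expected", {
  set.seed(1)
  truth <- rdirichlet_mat(10, c(4, 2, 1))
  base <- rdirichlet_mat(10, c(4, 2, 1))
  expect_equal(abd(truth, base, truth), -sum(abs(base - truth)))
  expect_lte(abd(truth, base, truth), 0)
  expect_equal(abd(base, base, truth), 0)
  expect_equal(as.numeric(rabd(base, base, truth)), 0)
  expect_equal(cd(base, base, truth), 0)
  expect_equal(cd(truth, base, truth),
               1 - cor(as.vector(base), as.vector(truth)))
})

test_that("ABD, rABD and CD are antisymmetric under swapping the estimators", {
  set.seed(2)
  truth <- rdirichlet_mat(12, c(3, 2, 1, 1))
  a <- rdirichlet_mat(12, c(3, 2, 1, 1))
  b <- rdirichlet_mat(12, c(2, 2, 2, 1))
  expect_identical(abd(a, b, truth), -abd(b, a, truth))
  expect_identical(cd(a, b, truth), -cd(b, a, truth))
  expect_equal(as.numeric(rabd(a, b, truth)), -as.numeric(rabd(b, a, truth)))
})

test_that("rABD excludes zero-truth entries and reports the count", {
  truth <- matrix(c(0.5, 0.5, 0, 0.25, 0.25, 0.5), 2, 3, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  cand <- matrix(c(0.4, 0.6, 0, 0.25, 0.25, 0.5), 2, 3, byrow = TRUE,
                 dimnames = dimnames(truth))
  r <- rabd(cand, truth, truth)
  expect_equal(attr(r, "n_excluded"), 1L)
  # only 5 entries averaged: candidate errs by 20% on two of them
  expect_equal(as.numeric(r), mean(c(0.2, 0.2, 0, 0, 0)) * 100)
})

test_that("CD equals an independent two-pass Pearson computation", {
  set.seed(3)
  truth <- rdirichlet_mat(20, c(4, 3, 2, 1))
  a <- rdirichlet_mat(20, c(4, 3, 2, 1))
  b <- rdirichlet_mat(20, c(1, 1, 1, 1))
  two_pass <- function(x, y) {
    x <- as.vector(x); y <- as.vector(y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cd(a, b, truth),
               two_pass(a, truth) - two_pass(b, truth), tolerance = 1e-12)
})

test_that("lin_ccc attains its bounds", {
  set.seed(4)
  x <- rdirichlet_mat(20, c(3, 2, 1))
  expect_equal(lin_ccc(x, x), 1)
  y <- -x + 2 * mean(x)  # perfect negative agreement about the common mean
  expect_equal(lin_ccc(x, y), -1)
  expect_equal(lin_ccc_euclidean(x, x), 1)
})

test_that("lin_ccc equals the classical closed form on random pairs", {
  set.seed(5)
  for (i in 1:50) {
    x <- as.vector(rdirichlet_mat(15, c(3, 2, 1, 1)))
    y <- as.vector(rdirichlet_mat(15, c(2, 2, 1, 2)))
    n <- length(x)
    sxy <- mean(x * y) - mean(x) * mean(y)
    sx2 <- mean(x^2) - mean(x)^2
    sy2 <- mean(y^2) - mean(y)^2
    classical <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
    expect_equal(lin_ccc(x, y), classical, tolerance = 1e-12)
  }
})

test_that("lin_ccc is symmetric and bounded on random inputs", {
  set.seed(6)
  for (i in 1:20) {
    x <- rdirichlet_mat(10, runif(4, 0.5, 4))
    y <- rdirichlet_mat(10, runif(4, 0.5, 4))
    for (f in list(lin_ccc, lin_ccc_euclidean, lin_ccc_aitchison)) {
      v <- f(x, y)
      expect_equal(v, f(y, x), tolerance = 1e-12)
      expect_gte(v, -1)
      expect_lte(v, 1)
    }
  }
})

test_that("lin_ccc rejects degenerate constant equal-mean input", {
  x <- matrix(0.5, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(lin_ccc(x, x), "degenerate")
})

test_that("evaluate_pair populates deltas as exact differences", {
  set.seed(7)
  truth <- rdirichlet_mat(15, c(4, 2, 1))
  base <- rdirichlet_mat(15, c(4, 2, 1))
  r <- evaluate_pair(truth, base, truth)
  expect_s3_class(r, "metric_report")
  expect_equal(r$delta_ccc, 1 - r$ccc_baseline)
  expect_equal(r$delta_ccc, r$ccc_candidate - r$ccc_baseline)
  expect_equal(r$delta_ccc_e, r$ccc_e_candidate - r$ccc_e_baseline)
  expect_equal(r$delta_ccc_e_percent,
               r$delta_ccc_e / r$ccc_e_baseline * 100)
  same <- evaluate_pair(base, base, truth)
  expect_equal(same$abd, 0)
  expect_equal(same$cd, 0)
  expect_equal(same$delta_ccc, 0)
  expect_equal(same$delta_ccc_e, 0)
})

test_that("metric report round-trips its scalars through TSV", {
  set.seed(8)
  truth <- rdirichlet_mat(10, c(3, 2, 1))
  r <- evaluate_pair(rdirichlet_mat(10, c(3, 2, 1)),
                     rdirichlet_mat(10, c(2, 2, 2)), truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(r, path)
  back <- read.delim(path)
  expect_equal(back$abd, r$abd, tolerance = 1e-12)
  expect_equal(back$delta_ccc_e, r$delta_ccc_e, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.tsv$", "_celltype.tsv", path)))
})
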