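# helper: simulate data straight from the stage II mixed model
lmm_dataset <- function(N = 20, t = 3, K = 3, m = c(10, 5, 1),
                        beta = rep(0, K), sigma_u = 0, sigma_e = 0,
                        seed = 1, balanced_groups = FALSE) {
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(N))
  z <- if (balanced_groups) rep(c(0, 1), length.out = N) else rep(0, N)
  names(z) <- subjects
  subject <- rep(subjects, each = t)
  n <- N * t
  theta <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(K, 2); g / sum(g)
  }, numeric(K)))
  colnames(theta) <- paste0("ct", seq_len(K))
  u <- matrix(rnorm(N * K, 0, sigma_u), N, K, dimnames = list(subjects, NULL))
  y <- vapply(seq_len(n), function(i) {
    s <- subject[i]
    sum((m + beta * z[s] + u[s, ]) * theta[i, ]) + rnorm(1, 0, sigma_e)
  }, numeric(1))
  list(y = y, theta = theta, subject = subject, z = z, u = u)
}

test_that("noise-free expression recovers fixed effects to 1e-6", {
  d <- lmm_dataset(N = 20, m = c(10, 5, 1), seed = 41)
  fit <- fit_gene_lmm(d$y, d$theta, d$subject, d$z)
  expect_s3_class(fit, "gene_lmm_fit")
  expect_equal(unname(fit$m_hat), c(10, 5, 1), tolerance = 1e-6)
  expect_equal(unname(fit$beta_hat), rep(0, 3), tolerance = 1e-6)
  expect_true(all(fit$varcomp < 1e-6))
})

test_that("K=1 with unit proportions reduces to the intercept model", {
  set.seed(42)
  N <- 10; t <- 3
  subjects <- sprintf("s%02d", 1:N)
  z <- rep(c(0, 1), length.out = N); names(z) <- subjects
  subject <- rep(subjects, each = t)
  y <- rnorm(N * t, mean = 20 + 3 * z[subject], sd = 0.5)
  theta <- matrix(1, N * t, 1, dimnames = list(NULL, "ct1"))
  fit <- fit_gene_lmm(y, theta, subject, z)
  # m_hat is the control-group mean under the random-intercept reduction
  ctrl <- subject %in% subjects[z == 0]
  # REML intercept of a balanced one-way design equals the group grand mean
  grand <- mean(tapply(y[ctrl], subject[ctrl], mean))
  expect_equal(unname(fit$m_hat), grand, tolerance = 1e-8)
})

test_that("simulated random slopes are recovered without bias", {
  # Monte-Carlo over genes at one shared design: the average of m_hat and
  # beta_hat across genes must sit within 2 Monte-Carlo SEs of the truth
  set.seed(43)
  N <- 30; t <- 3; K <- 3
  # sigma_u must dominate the residual scale for BLUPs to be informative
  m <- c(12, 6, 2); beta <- c(2, -1, 0); sigma_u <- 3; sigma_e <- 0.5
  n_genes <- 60
  d0 <- lmm_dataset(N = N, t = t, K = K, seed = 44, balanced_groups = TRUE)
  M <- matrix(NA_real_, n_genes, K)
  B <- matrix(NA_real_, n_genes, K)
  cors <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    u <- matrix(rnorm(N * K, 0, sigma_u), N, K,
                dimnames = list(unique(d0$subject), NULL))
    y <- vapply(seq_along(d0$y), function(i) {
      s <- d0$subject[i]
      sum((m + beta * d0$z[s] + u[s, ]) * d0$theta[i, ]) + rnorm(1, 0, sigma_e)
    }, numeric(1))
    fit <- fit_gene_lmm(y, d0$theta, d0$subject, d0$z)
    M[g, ] <- fit$m_hat; B[g, ] <- fit$beta_hat
    cors[g] <- cor(as.vector(fit$u_hat), as.vector(u))
  }
  # 6 simultaneous checks: Bonferroni-adjusted normal bound at overall ~5%
  bound <- qnorm(1 - 0.025 / (2 * K))
  for (k in seq_len(K)) {
    expect_lt(abs(mean(M[, k]) - m[k]), bound * sd(M[, k]) / sqrt(n_genes))
    expect_lt(abs(mean(B[, k]) - beta[k]), bound * sd(B[, k]) / sqrt(n_genes))
  }
  # BLUPs track the true deviations when sigma_u dominates
  expect_gt(mean(cors), 0.5)
})

test_that("panel assembly follows m + z*beta + u with clipping", {
  fit <- structure(list(
    m_hat = c(ct1 = 5), beta_hat = c(ct1 = 2),
    u_hat = matrix(-1, 1, 1, dimnames = list("subj", "ct1")),
    varcomp = c(ct1 = 1), resid_var = 1, converged = TRUE,
    fallback = "none", dropped_interactions = character()),
    class = "gene_lmm_fit")
  expect_equal(unname(assemble_subject_panel(fit, "subj", z = 1)), 6)
  expect_equal(unname(assemble_subject_panel(fit, "subj", z = 0)), 4)
  fit$m_hat <- c(ct1 = 1); fit$beta_hat <- c(ct1 = -3)
  fit$u_hat[1, 1] <- 0
  expect_equal(unname(assemble_subject_panel(fit, "subj", z = 1)), 0)
  expect_error(assemble_subject_panel(fit, "nobody", 0), "unknown subject")
})

test_that("control-group panels equal m_hat + u_hat exactly before clipping", {
  d <- lmm_dataset(N = 12, sigma_u = 2, sigma_e = 0.5, seed = 45,
                   balanced_groups = TRUE)
  fit <- fit_gene_lmm(d$y, d$theta, d$subject, d$z)
  for (s in names(d$z)[d$z == 0]) {
    expect_equal(assemble_subject_panel(fit, s, 0),
                 pmax(fit$m_hat + fit$u_hat[s, ], 0), tolerance = 1e-10)
  }
})

test_that("zero variance components force exactly zero BLUPs", {
  d <- lmm_dataset(N = 15, sigma_u = 0, sigma_e = 1, seed = 46)
  fit <- fit_gene_lmm(d$y, d$theta, d$subject, d$z)
  expect_true(all(fit$varcomp >= 0))
  zero_vc <- fit$varcomp == 0
  if (any(zero_vc))
    expect_true(all(fit$u_hat[, zero_vc] == 0))
})

test_that("identical subjects yield negligible random deviations", {
  sim <- simulate_deconv_data(small_sim_config(seed = 47, ssv_range = c(0, 0)))
  # all subjects in a group share the same panel; u should be ~0
  s1 <- proportion_set(unclass(sim$theta_T), "truth")
  panels <- run_stage2(sim$bulk, s1, genes = rownames(sim$signature)[1:40])
  u_mag <- vapply(panels$fits, function(f) max(abs(f$u_hat)), numeric(1))
  m_mag <- vapply(panels$fits, function(f) mean(abs(f$m_hat)), numeric(1))
  expect_lt(median(u_mag / m_mag), 0.05)
})

test_that("gene-wise fits are order invariant", {
  sim <- simulate_deconv_data(small_sim_config(seed = 48))
  s1 <- run_stage1(sim$bulk, sim$signature)
  genes <- rownames(sim$signature)[1:12]
  a <- run_stage2(sim$bulk, s1, genes = genes)
  b <- run_stage2(sim$bulk, s1, genes = rev(genes))
  s <- names(a$panels)[1]
  expect_equal(a$panels[[s]][genes, ], b$panels[[s]][genes, ],
               tolerance = 1e-12)
})

test_that("single-sample subjects are rejected with advice", {
  bulk <- make_bulk(G = 10, subjects = c("a", "b"), repeats = 2)
  # drop one of a's samples
  keep <- bulk$samples$sample_id != "a_r2"
  bulk2 <- bulk_experiment(bulk$expression[, keep],
                           bulk$samples[keep, ])
  theta <- rdirichlet_mat(3, c(2, 2, 2))
  rownames(theta) <- colnames(bulk2$expression)
  expect_error(run_stage2(bulk2, theta), "repeated measures")
})

test_that("aliased interactions are dropped instead of failing", {
  d <- lmm_dataset(N = 12, sigma_e = 0.5, seed = 49)  # all z = 0
  fit <- fit_gene_lmm(d$y, d$theta, d$subject, d$z)
  # with no case subjects every interaction column is aliased
  expect_length(fit$dropped_interactions, 3)
  expect_equal(unname(fit$beta_hat), rep(0, 3))
})
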