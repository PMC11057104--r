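test_that("DE mask marks exactly ceiling(de_fraction * G) genes per cell type", {
  cfg <- sim_config(seed = 51)
  set.seed(cfg$seed)
  pars <- draw_cts_parameters(cfg)
  expect_equal(unname(colSums(pars$de_mask)), c(100, 100, 100, 100, 0, 0))
  expect_equal(pars$M_case[pars$de_mask],
               pars$M_ctrl[pars$de_mask] + cfg$lfc)
  expect_equal(pars$M_case[!pars$de_mask], pars$M_ctrl[!pars$de_mask])
})

test_that("a null effect size leaves the case means untouched", {
  cfg <- sim_config(lfc = 0, n_genes = 200, n_markers = 100, seed = 52)
  set.seed(cfg$seed)
  pars <- draw_cts_parameters(cfg)
  expect_identical(pars$M_case, pars$M_ctrl)
  panels <- draw_expression_panels(pars$M_ctrl, pars$M_case, pars$Phi, cfg)
  expect_identical(panels$P_case, panels$P_ctrl)
})

test_that("log-mean draws reproduce the configured cross-cell-type correlation", {
  cfg <- sim_config(n_genes = 1000, seed = 53)
  set.seed(cfg$seed)
  pars <- draw_cts_parameters(cfg)
  target <- cov2cor(cfg$mvn_cov_logmean)
  observed <- cor(pars$M_ctrl)
  expect_lt(max(abs(observed - target)), 0.1)
})

test_that("Gamma panel moments match mean = exp(M) and CV^2 = exp(Phi)", {
  set.seed(54)
  n <- 1e5
  M <- log(50); Phi <- log(0.1)
  draws <- rgamma(n, shape = 1 / exp(Phi), scale = exp(M) * exp(Phi))
  se_mean <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - 50), 3 * se_mean)
  cv2 <- var(draws) / mean(draws)^2
  expect_lt(abs(cv2 - 0.1), 0.01)
})

test_that("zero subject variation copies the group panel exactly", {
  cfg <- sim_config(n_genes = 100, n_subjects_per_group = 3,
                    ssv_range = c(0, 0), n_markers = 50, seed = 55)
  set.seed(cfg$seed)
  pars <- draw_cts_parameters(cfg)
  panels <- draw_expression_panels(pars$M_ctrl, pars$M_case, pars$Phi, cfg)
  expect_equal(panels$P_n[["ctrl001"]], panels$P_ctrl)
  expect_equal(panels$P_n[["case002"]], panels$P_case)
})

test_that("subject panels stay within the configured variation band", {
  cfg <- sim_config(n_genes = 100, n_subjects_per_group = 4,
                    ssv_range = c(0.05, 0.1), n_markers = 50, seed = 56)
  set.seed(cfg$seed)
  pars <- draw_cts_parameters(cfg)
  panels <- draw_expression_panels(pars$M_ctrl, pars$M_case, pars$Phi, cfg)
  rel <- abs(panels$P_n[["ctrl001"]] / panels$P_ctrl - 1)
  expect_gte(min(rel), 0.05 - 1e-12)
  expect_lte(max(rel), 0.1 + 1e-12)
})

test_that("proportions, Poisson means and counts are mutually consistent", {
  sim <- simulate_deconv_data(small_sim_config(seed = 57))
  cfg <- sim$config
  n_samples <- 2 * cfg$n_subjects_per_group * cfg$repeats_per_subject
  expect_equal(dim(sim$bulk$expression), c(cfg$n_genes, n_samples))
  expect_equal(unname(rowSums(sim$theta_T)), rep(1, n_samples),
               tolerance = 1e-12)
  # conservation: lambda column sums equal sum_k theta_k * colsum(P_n[, k])
  for (j in c(1, 10, n_samples)) {
    s <- sim$bulk$samples$subject_id[j]
    expect_equal(sum(sim$lambda[, j]),
                 sum(colSums(sim$P_n[[s]]) * sim$theta_T[j, ]),
                 tolerance = 1e-9)
  }
})

test_that("extreme Dirichlet concentration collapses to the uniform simplex", {
  cfg <- small_sim_config(seed = 58, alpha_ctrl = rep(1e6, 3),
                          alpha_case = rep(1e6, 3))
  sim <- simulate_deconv_data(cfg)
  expect_lt(max(abs(sim$theta_T - 1 / 3)), 0.01)
})

test_that("Poisson and Dirichlet sampling match their first moments", {
  set.seed(59)
  y <- rpois(1e4, 40)
  expect_lt(abs(mean(y) - 40), 3 * sqrt(40 / 1e4))
  alpha <- c(4, 2, 1)
  th <- t(vapply(1:5000, function(i) {
    g <- rgamma(3, alpha); g / sum(g)
  }, numeric(3)))
  expect_lt(max(abs(colMeans(th) - alpha / sum(alpha))), 3 * 0.3 / sqrt(5000))
})

test_that("marker selection ranks by coefficient of variation", {
  P <- matrix(c(5, 5, 5,      # cv 0
                1, 5, 9,      # high cv
                4, 5, 6,      # low cv
                2, 5, 8),     # medium cv
              4, 3, byrow = TRUE,
              dimnames = list(c("flat", "sharp", "mild", "medium"),
                              paste0("ct", 1:3)))
  sig <- build_signature(list(P), n_markers = 3)
  # a zero-CV gene is never selected before genes with spread
  expect_identical(rownames(sig), c("sharp", "medium", "mild"))
  all4 <- build_signature(list(P), n_markers = 4)
  expect_identical(rownames(all4), c("sharp", "medium", "mild", "flat"))
  expect_error(build_signature(list(P), n_markers = 5), "exceeds")
})

test_that("identical seed and config give bit-identical simulations", {
  a <- simulate_deconv_data(small_sim_config(seed = 60))
  b <- simulate_deconv_data(small_sim_config(seed = 60))
  expect_identical(a$bulk$expression, b$bulk$expression)
  expect_identical(unclass(a$theta_T), unclass(b$theta_T))
  expect_identical(a$P_n, b$P_n)
  expect_identical(rownames(a$signature), rownames(b$signature))
  c <- simulate_deconv_data(small_sim_config(seed = 61))
  expect_false(identical(a$bulk$expression, c$bulk$expression))
})

test_that("config validation rejects malformed settings", {
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(ssv_range = c(0.2, 0.1)), "ssv_range")
  expect_error(sim_config(alpha_ctrl = c(1, -1, 1, 1, 1, 1)), "positive")
  expect_error(sim_config(n_markers = 2000), "n_markers")
  bad_cov <- matrix(c(1, 2, 2, 1), 2, 2)  # not PSD
  expect_error(sim_config(n_celltypes = 2, de_celltypes = 1,
                          mvn_cov_logmean = bad_cov,
                          alpha_ctrl = c(2, 1), alpha_case = c(2, 1),
                          mvn_mean_logmean = c(4, 3)),
               "positive semi-definite")
})

test_that("YAML configs round-trip through read_sim_config", {
  cfg <- small_sim_config(seed = 62)
  dir <- withr::local_tempdir()
  sim <- simulate_deconv_data(cfg)
  write_simulation(sim, dir)
  cfg2 <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$mvn_cov_logmean, cfg$mvn_cov_logmean)
  expect_equal(cfg2$alpha_ctrl, cfg$alpha_ctrl)
  expect_equal(cfg2$seed, cfg$seed)
  # simulating from the echoed config reproduces the dataset
  sim2 <- simulate_deconv_data(cfg2)
  expect_identical(sim$bulk$expression, sim2$bulk$expression)
  expect_error(read_sim_config(textConnection("nope: 1")))
})
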