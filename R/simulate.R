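#' Configuration for the longitudinal bulk RNA-seq simulator
#'
#' The simulator emulates a two-group repeated-measures bulk RNA-seq study of
#' a tissue mixing `n_celltypes` cell types. Per gene, log-scale cell-type
#' expression means and log-dispersions are drawn from multivariate normals
#' correlated across cell types; group-level cell-type-specific expression
#' panels are Gamma draws around those means; differential expression of
#' log-fold-change `lfc` is injected into a fraction `de_fraction` of genes in
#' the cell types `de_celltypes`; each subject's panel deviates from its group
#' panel by a symmetric multiplicative subject-to-subject variation (SSV) drawn
#' from `ssv_range`; per-sample cell-type proportions are Dirichlet; observed
#' counts are Poisson around the panel-times-proportions mean.
#'
#' Defaults not fixed by the study design (the MVN means/covariances and the
#' Dirichlet concentrations) are documented stand-ins: log-means evenly spaced
#' over [2, 6] with cross-cell-type correlation 0.8 (unit variances),
#' log-dispersions centred at log(0.15) with correlation 0.5 (sd 0.5), and
#' control concentrations decreasing from 12 to 1 scaled by 0.8 with the case
#' group an alternating +/-15% perturbation. All are overridable here or from
#' a YAML config (see [read_sim_config()]).
#'
#' @param n_genes Number of genes G.
#' @param n_celltypes Number of cell types K.
#' @param n_subjects_per_group Subjects per group N (total 2N).
#' @param repeats_per_subject Repeated measures per subject t.
#' @param lfc Differential-expression log-fold-change Delta.
#' @param de_fraction Fraction of genes made DE per affected cell type.
#' @param de_celltypes Indices of cell types receiving DE genes.
#' @param ssv_range Length-2 range `[lo, hi]` of the SSV percentage (e.g.
#'   `c(0, 0.05)` for up to 5% deviation).
#' @param mvn_mean_logmean,mvn_cov_logmean Mean vector / covariance of the
#'   per-gene log-expression-means across cell types.
#' @param mvn_mean_logdisp,mvn_cov_logdisp Same for log-dispersions.
#' @param alpha_ctrl,alpha_case Dirichlet concentration vectors.
#' @param n_markers Number of top coefficient-of-variation marker genes kept
#'   in the simulated signature matrix.
#' @param seed Integer RNG seed; the whole simulation is a single seeded
#'   stream, so identical config + seed reproduces the dataset exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_celltypes = 6,
                       n_subjects_per_group = 100, repeats_per_subject = 3,
                       lfc = 0.5, de_fraction = 0.10,
                       de_celltypes = 1:4, ssv_range = c(0, 0.05),
                       mvn_mean_logmean = NULL, mvn_cov_logmean = NULL,
                       mvn_mean_logdisp = NULL, mvn_cov_logdisp = NULL,
                       alpha_ctrl = NULL, alpha_case = NULL,
                       n_markers = 300, seed = 1L) {
  K <- n_celltypes
  if (is.null(mvn_mean_logmean))
    mvn_mean_logmean <- seq(2, 6, length.out = K)
  if (is.null(mvn_cov_logmean))
    mvn_cov_logmean <- equicor_cov(K, sd = 2, rho = 0.8)
  if (is.null(mvn_mean_logdisp))
    mvn_mean_logdisp <- rep(log(0.15), K)
  if (is.null(mvn_cov_logdisp))
    mvn_cov_logdisp <- equicor_cov(K, sd = 0.5, rho = 0.5)
  if (is.null(alpha_ctrl))
    alpha_ctrl <- rev(seq(1, 12, length.out = K)) * 0.8
  if (is.null(alpha_case))
    alpha_case <- alpha_ctrl * (1 + 0.15 * rep_len(c(-1, 1), K))

  cfg <- list(n_genes = as.integer(n_genes), n_celltypes = as.integer(K),
              n_subjects_per_group = as.integer(n_subjects_per_group),
              repeats_per_subject = as.integer(repeats_per_subject),
              lfc = lfc, de_fraction = de_fraction,
              de_celltypes = as.integer(de_celltypes),
              ssv_range = as.numeric(ssv_range),
              mvn_mean_logmean = as.numeric(mvn_mean_logmean),
              mvn_cov_logmean = as.matrix(mvn_cov_logmean),
              mvn_mean_logdisp = as.numeric(mvn_mean_logdisp),
              mvn_cov_logdisp = as.matrix(mvn_cov_logdisp),
              alpha_ctrl = as.numeric(alpha_ctrl),
              alpha_case = as.numeric(alpha_case),
              n_markers = as.integer(n_markers), seed = as.integer(seed))

  stopifnot(cfg$n_genes > 0, K >= 2, cfg$n_subjects_per_group > 0,
            cfg$repeats_per_subject >= 1)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (length(cfg$de_celltypes) &&
      (any(cfg$de_celltypes < 1) || any(cfg$de_celltypes > K)))
    stop("de_celltypes out of range 1..K")
  if (length(cfg$ssv_range) != 2 || cfg$ssv_range[1] < 0 ||
      diff(cfg$ssv_range) < 0)
    stop("ssv_range must be 0 <= lo <= hi")
  for (nm in c("mvn_cov_logmean", "mvn_cov_logdisp")) {
    S <- cfg[[nm]]
    if (!isSymmetric(S) || any(eigen(S, symmetric = TRUE,
                                     only.values = TRUE)$values < -1e-10))
      stop(nm, " must be a symmetric positive semi-definite KxK matrix")
  }
  if (any(cfg$alpha_ctrl <= 0) || any(cfg$alpha_case <= 0))
    stop("Dirichlet concentrations must be positive")
  if (length(cfg$mvn_mean_logmean) != K || length(cfg$alpha_ctrl) != K ||
      length(cfg$alpha_case) != K || nrow(cfg$mvn_cov_logmean) != K)
    stop("parameter dimensions must match n_celltypes")
  if (cfg$n_markers > cfg$n_genes)
    stop("n_markers cannot exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

# internal: equicorrelated covariance with common sd
equicor_cov <- function(K, sd, rho) {
  S <- matrix(rho, K, K); diag(S) <- 1
  S * sd^2
}

#' Read a simulator configuration from YAML
#'
#' Any field of [sim_config()] may appear in the YAML file; covariance
#' matrices are given as nested lists of rows. Missing fields take the
#' documented defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown simulator config field(s): ", paste(unknown, collapse = ", "))
  for (nm in c("mvn_cov_logmean", "mvn_cov_logdisp"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- do.call(rbind, raw[[nm]])
  do.call(sim_config, raw)
}

#' Draw per-gene cell-type-specific expression parameters
#'
#' Per gene, the K-vector of log-means is drawn from
#' MVN(`mvn_mean_logmean`, `mvn_cov_logmean`) and the K-vector of
#' log-dispersions from MVN(`mvn_mean_logdisp`, `mvn_cov_logdisp`). A DE mask
#' marks `ceiling(de_fraction * G)` genes per affected cell type (sampled
#' without replacement, independently across cell types, so sets may overlap);
#' the case-group log-means are the control log-means plus `lfc` on the mask.
#'
#' @param cfg A [sim_config()]. Uses the current RNG state; seed via
#'   [simulate_deconv_data()] or `set.seed()`.
#' @return List with `M_ctrl`, `M_case`, `Phi` (G x K), `de_mask` (logical
#'   G x K).
#' @export
draw_cts_parameters <- function(cfg) {
  G <- cfg$n_genes; K <- cfg$n_celltypes
  gn <- sprintf("gene%04d", seq_len(G))
  ct <- paste0("ct", seq_len(K))
  M <- MASS::mvrnorm(G, cfg$mvn_mean_logmean, cfg$mvn_cov_logmean)
  Phi <- MASS::mvrnorm(G, cfg$mvn_mean_logdisp, cfg$mvn_cov_logdisp)
  dimnames(M) <- dimnames(Phi) <- list(gn, ct)
  de_mask <- matrix(FALSE, G, K, dimnames = list(gn, ct))
  n_de <- ceiling(cfg$de_fraction * G)
  for (k in cfg$de_celltypes)
    de_mask[sample.int(G, n_de), k] <- TRUE
  M_case <- M + cfg$lfc * de_mask
  list(M_ctrl = M, M_case = M_case, Phi = Phi, de_mask = de_mask)
}

#' Draw group-level and subject-level expression panels
#'
#' Group panels are entrywise Gamma with shape `1/exp(Phi)` and scale
#' `exp(M) * exp(Phi)` (so the mean is `exp(M)` and the squared coefficient of
#' variation `exp(Phi)`). The two groups share one Gamma realization — the
#' case panel is the control panel scaled entrywise by
#' `exp(M_case - M_ctrl)`, a comonotone coupling under which both marginals
#' are exactly the stated Gammas and the groups differ only where the DE mask
#' put a log-fold-change. (Independent draws would make every gene's panel
#' differ between groups by the full biological coefficient of variation,
#' contradicting the injected-DE design.) Each subject's panel multiplies its
#' group panel by `1 + s * delta` with `delta ~ Uniform(ssv_range)` and a
#' random sign `s`, independently per (gene, subject, cell type).
#'
#' @param M_ctrl,M_case,Phi G x K parameter matrices from
#'   [draw_cts_parameters()].
#' @param cfg A [sim_config()].
#' @return List with `P_ctrl`, `P_case` (G x K) and `P_n` (named list,
#'   subject -> G x K), subjects named `ctrl###` / `case###`.
#' @export
draw_expression_panels <- function(M_ctrl, M_case, Phi, cfg) {
  G <- cfg$n_genes; K <- cfg$n_celltypes
  shape <- 1 / exp(Phi)
  P_ctrl <- matrix(rgamma(G * K, shape = shape, scale = exp(M_ctrl) * exp(Phi)),
                   G, K, dimnames = dimnames(M_ctrl))
  # comonotone coupling: same Gamma quantile in both groups, so the case
  # marginal is Gamma with mean exp(M_case) and the groups coincide off the
  # DE mask (Gamma is a scale family in its scale parameter)
  P_case <- P_ctrl * exp(M_case - M_ctrl)
  N <- cfg$n_subjects_per_group
  subjects <- c(sprintf("ctrl%03d", seq_len(N)), sprintf("case%03d", seq_len(N)))
  P_n <- lapply(subjects, function(s) {
    base <- if (startsWith(s, "ctrl")) P_ctrl else P_case
    delta <- matrix(runif(G * K, cfg$ssv_range[1], cfg$ssv_range[2]), G, K)
    sgn <- matrix(sample(c(-1, 1), G * K, replace = TRUE), G, K)
    base * (1 + sgn * delta)
  })
  names(P_n) <- subjects
  list(P_ctrl = P_ctrl, P_case = P_case, P_n = P_n)
}

#' Draw per-sample proportions, Poisson means and observed counts
#'
#' One Dirichlet draw per sample (concentration by group) gives the true
#' cell-type proportions; the Poisson mean of sample i of subject n is
#' `lambda = P_n %*% theta`; observed counts are Poisson around it.
#'
#' @param P_n Named list of subject panels from [draw_expression_panels()].
#' @param cfg A [sim_config()].
#' @return List with `theta_T` (a [proportion_set()], origin `"truth"`),
#'   `lambda` (G x T matrix) and `bulk` (a [bulk_experiment()] of counts).
#' @export
draw_proportions_and_counts <- function(P_n, cfg) {
  G <- cfg$n_genes; K <- cfg$n_celltypes; t <- cfg$repeats_per_subject
  subjects <- names(P_n)
  samples <- as.vector(t(outer(subjects, seq_len(t), paste, sep = "_s")))
  md <- data.frame(sample_id = samples,
                   subject_id = rep(subjects, each = t),
                   repeat_index = rep(seq_len(t), length(subjects)),
                   group = as.integer(startsWith(rep(subjects, each = t), "case")))
  ct <- colnames(P_n[[1]])
  theta <- matrix(NA_real_, length(samples), K, dimnames = list(samples, ct))
  lambda <- matrix(NA_real_, G, length(samples),
                   dimnames = list(rownames(P_n[[1]]), samples))
  counts <- lambda
  for (j in seq_along(samples)) {
    s <- md$subject_id[j]
    alpha <- if (md$group[j] == 1) cfg$alpha_case else cfg$alpha_ctrl
    th <- rdirichlet1(alpha)
    theta[j, ] <- th
    lam <- drop(P_n[[s]] %*% th)
    lambda[, j] <- lam
    counts[, j] <- rpois(G, lam)
  }
  list(theta_T = proportion_set(theta, "truth"), lambda = lambda,
       bulk = bulk_experiment(counts, md))
}

# internal: one Dirichlet draw via normalized Gamma variates
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Build the population signature matrix from subject panels
#'
#' Averages the subject panels gene-wise, ranks genes by the coefficient of
#' variation of the averaged expression across cell types, and keeps the top
#' `n_markers` as pseudo-marker genes.
#'
#' @param P_n Named list of subject panels (G x K each).
#' @param n_markers Number of marker genes to keep.
#' @return A [signature_matrix()] of dimension `n_markers` x K.
#' @export
build_signature <- function(P_n, n_markers) {
  mean_panel <- Reduce(`+`, P_n) / length(P_n)
  if (n_markers > nrow(mean_panel))
    stop("n_markers exceeds the number of genes")
  mu <- rowMeans(mean_panel)
  sdv <- apply(mean_panel, 1, sd)
  cv <- ifelse(mu > 0, sdv / mu, 0)
  keep <- order(cv, decreasing = TRUE)[seq_len(n_markers)]
  signature_matrix(mean_panel[keep, , drop = FALSE])
}

#' Simulate a longitudinal bulk RNA-seq dataset with full ground truth
#'
#' Runs the whole generative chain — per-gene MVN parameters, Gamma expression
#' panels with subject-to-subject variation, Dirichlet proportions, Poisson
#' counts, and coefficient-of-variation marker selection — in one seeded RNG
#' stream.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_truth` holding every latent quantity:
#'   `M_ctrl`, `M_case`, `Phi`, `de_mask`, `P_ctrl`, `P_case`, `P_n`,
#'   `theta_T`, `lambda`, `bulk`, `signature` and the `config`.
#' @examples
#' sim <- simulate_deconv_data(sim_config(n_genes = 60, n_subjects_per_group = 4,
#'                                        n_markers = 30, seed = 7))
#' sim$bulk
#' @export
simulate_deconv_data <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pars <- draw_cts_parameters(cfg)
  panels <- draw_expression_panels(pars$M_ctrl, pars$M_case, pars$Phi, cfg)
  obs <- draw_proportions_and_counts(panels$P_n, cfg)
  sig <- build_signature(panels$P_n, cfg$n_markers)
  structure(c(pars, panels, obs, list(signature = sig, config = cfg)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "sim_truth: %d genes x %d samples (%d+%d subjects x %d repeats), K=%d\n",
    cfg$n_genes, ncol(x$bulk$expression), cfg$n_subjects_per_group,
    cfg$n_subjects_per_group, cfg$repeats_per_subject, cfg$n_celltypes))
  cat(sprintf("  LFC=%.2f on %.0f%% of genes in cell types {%s}; SSV in [%g, %g]; %d markers; seed %d\n",
              cfg$lfc, 100 * cfg$de_fraction,
              paste(cfg$de_celltypes, collapse = ","),
              cfg$ssv_range[1], cfg$ssv_range[2], cfg$n_markers, cfg$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the observable artifacts (bulk counts TSV, metadata TSV, signature
#' TSV) and the truth bundle (true proportions, per-subject panels, DE mask,
#' config echo as YAML) into a directory.
#'
#' @param sim A `sim_truth` from [simulate_deconv_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(m, f, id_col) {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    names(df)[1] <- id_col
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(sim$bulk$expression, "bulk.tsv", "gene")
  write.table(sim$bulk$samples, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wt(unclass(sim$signature), "signature.tsv", "gene")
  write_proportions(sim$theta_T, file.path(dir, "theta_truth.tsv"))
  wt(sim$de_mask * 1L, "de_mask.tsv", "gene")
  truth_dir <- file.path(dir, "panels_truth")
  dir.create(truth_dir, showWarnings = FALSE)
  for (s in names(sim$P_n)) {
    wt2 <- data.frame(gene = rownames(sim$P_n[[s]]), sim$P_n[[s]],
                      check.names = FALSE)
    write.table(wt2, file.path(truth_dir, paste0("panel_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- sim$config
  cfg$mvn_cov_logmean <- apply(cfg$mvn_cov_logmean, 1, as.numeric,
                               simplify = FALSE)
  cfg$mvn_cov_logdisp <- apply(cfg$mvn_cov_logdisp, 1, as.numeric,
                               simplify = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
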