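#' Fit the per-gene linear mixed-effect model
#'
#' Stage II models one gene's expression across all samples as a mixture over
#' cell types whose weights are the Stage I proportions:
#' \deqn{E(y_{ni}) = \sum_k (m_k + \beta_k z_n + u_{nk})\,\hat\theta_{nik}}
#' with fixed cell-type means \eqn{m_k} (control group), fixed case-control
#' differences \eqn{\beta_k}, and subject-level random slopes \eqn{u_{nk}} on
#' the proportions with diagonal covariance (one variance per cell type, no
#' cross-cell-type correlation and no random intercept — the model has no
#' fixed intercept either, since the proportions sum to one). Fitting is by
#' REML through \pkg{lme4}; the \eqn{\hat u_{nk}} are the BLUPs.
#'
#' Aliased interaction columns (e.g. a cell type with all-zero proportions in
#' one group) are detected on the fixed part and dropped before the mixed fit;
#' total non-convergence falls back to ordinary least squares on the fixed
#' part with all random effects at zero, recorded in `fallback`.
#'
#' @param y_g Numeric vector: the gene's expression, one entry per sample.
#' @param theta Samples x cell-types proportion matrix, rows aligned with
#'   `y_g` (Stage I output, or truth when testing).
#' @param subject Character/factor vector of subject ids per sample.
#' @param group Named vector of 0/1 group labels per subject.
#' @param covariates Optional numeric matrix (samples x covariates); each
#'   covariate enters as additional fixed interactions with the proportion
#'   columns.
#' @return A list of class `gene_lmm_fit`: `m_hat`, `beta_hat` (length-K
#'   vectors), `u_hat` (subjects x K BLUP matrix), `varcomp` (K random-slope
#'   variances), `resid_var`, `converged`, `fallback` (`"none"` or
#'   `"fixed_only"`), `dropped_interactions`.
#' @export
fit_gene_lmm <- function(y_g, theta, subject, group, covariates = NULL) {
  theta <- as.matrix(theta)
  K <- ncol(theta)
  n <- length(y_g)
  if (nrow(theta) != n || length(subject) != n)
    stop("y_g, theta rows and subject must have equal length")
  subject <- as.character(subject)
  subjects <- unique(subject)
  if (length(subjects) < 2 || any(table(subject) < 2))
    stop("every subject needs >= 2 samples and >= 2 subjects are required")
  z <- as.numeric(group[subject])
  if (anyNA(z)) stop("group label missing for some subject")
  cell_types <- colnames(theta)
  if (is.null(cell_types)) cell_types <- paste0("ct", seq_len(K))

  thn <- paste0("th", seq_len(K))
  df <- data.frame(y = y_g, z = z, subject = factor(subject, levels = subjects))
  for (k in seq_len(K)) df[[thn[k]]] <- theta[, k]

  # fixed part: K slopes + K interactions (+ optional covariate interactions)
  fixed_terms <- c(thn, paste0(thn, ":z"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cvn <- colnames(covariates)
    if (is.null(cvn)) cvn <- paste0("x", seq_len(ncol(covariates)))
    for (j in seq_along(cvn)) df[[cvn[j]]] <- covariates[, j]
    fixed_terms <- c(fixed_terms, as.vector(outer(thn, cvn, paste, sep = ":")))
  }

  # detect aliased columns on the fixed design; drop interactions first
  X <- model.matrix(stats::reformulate(fixed_terms, intercept = FALSE), df)
  ols <- lm.fit(X, y_g)
  aliased <- colnames(X)[is.na(ols$coefficients)]
  dropped <- intersect(aliased, setdiff(colnames(X), thn))
  fixed_kept <- setdiff(fixed_terms, dropped)

  # random slopes only for cell types with any variation
  re_ok <- apply(theta, 2, function(col) any(col != 0))
  re_terms <- sprintf("(0 + %s | subject)", thn[re_ok])

  form <- stats::as.formula(paste(
    "y ~ 0 +", paste(c(fixed_kept, re_terms), collapse = " + ")))

  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      form, data = df, REML = TRUE,
      control = lme4::lmerControl(
        calc.derivs = FALSE,
        check.conv.singular = "ignore",
        optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8, maxeval = 1000)))),
    error = function(e) NULL)

  if (is.null(fit)) {
    # OLS fallback: fixed effects only, random part zeroed
    co <- ols$coefficients
    m_hat <- unname(co[thn]); m_hat[is.na(m_hat)] <- 0
    beta_hat <- unname(co[paste0(thn, ":z")]); beta_hat[is.na(beta_hat)] <- 0
    return(structure(list(
      m_hat = setNames(m_hat, cell_types),
      beta_hat = setNames(beta_hat, cell_types),
      u_hat = matrix(0, length(subjects), K,
                     dimnames = list(subjects, cell_types)),
      varcomp = setNames(rep(0, K), cell_types),
      resid_var = sum(ols$residuals^2) / max(1, n - ols$rank),
      converged = FALSE, fallback = "fixed_only",
      dropped_interactions = dropped), class = "gene_lmm_fit"))
  }

  fe <- lme4::fixef(fit)
  m_hat <- setNames(rep(0, K), cell_types)
  beta_hat <- setNames(rep(0, K), cell_types)
  for (k in seq_len(K)) {
    if (thn[k] %in% names(fe)) m_hat[k] <- fe[[thn[k]]]
    nm <- intersect(c(paste0(thn[k], ":z"), paste0("z:", thn[k])), names(fe))
    if (length(nm)) beta_hat[k] <- fe[[nm[1]]]
  }

  u_hat <- matrix(0, length(subjects), K,
                  dimnames = list(subjects, cell_types))
  u_df <- lme4::ranef(fit)$subject  # one data frame, columns th1..thK
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(rep(0, K), cell_types)
  for (k in which(re_ok)) {
    if (thn[k] %in% colnames(u_df))
      u_hat[rownames(u_df), k] <- u_df[[thn[k]]]
    v <- vc$vcov[!is.na(vc$var1) & vc$var1 == thn[k] & is.na(vc$var2)]
    if (length(v)) varcomp[k] <- max(0, v[1])
    if (varcomp[k] == 0) u_hat[, k] <- 0  # zero variance => BLUPs exactly zero
  }
  resid_var <- vc$vcov[vc$grp == "Residual"][1]

  structure(list(m_hat = m_hat, beta_hat = beta_hat, u_hat = u_hat,
                 varcomp = varcomp, resid_var = resid_var,
                 converged = TRUE, fallback = "none",
                 dropped_interactions = dropped),
            class = "gene_lmm_fit")
}

#' Assemble one subject's reference expression for a gene
#'
#' The personalized reference expression of subject *n* in cell type *k* is
#' \eqn{r_{nk} = \hat m_k + z_n \hat\beta_k + \hat u_{nk}}, with negative
#' values clipped to zero.
#'
#' @param fit A `gene_lmm_fit` from [fit_gene_lmm()].
#' @param subject Subject id (must be present in the fit).
#' @param z The subject's 0/1 group label.
#' @return Named non-negative vector over cell types.
#' @export
assemble_subject_panel <- function(fit, subject, z) {
  stopifnot(inherits(fit, "gene_lmm_fit"))
  if (!subject %in% rownames(fit$u_hat))
    stop("unknown subject: ", subject)
  pmax(fit$m_hat + z * fit$beta_hat + fit$u_hat[subject, ], 0)
}

#' Stage II: recover personalized reference panels
#'
#' Fits [fit_gene_lmm()] independently for every gene (the fits share no
#' state, so results are invariant to gene order) and assembles, for each
#' subject, a genes x cell-types personalized reference panel via
#' [assemble_subject_panel()].
#'
#' @param bulk A [bulk_experiment()] (expression on the scale Stage III will
#'   deconvolve, e.g. CPM).
#' @param theta A [proportion_set()] aligned with the bulk samples (Stage I
#'   output, or ground truth when testing).
#' @param genes Character vector of gene ids to fit (default: all genes of the
#'   bulk; the [persdecon()] driver passes the signature's marker genes).
#' @param covariates Optional samples x covariates numeric matrix.
#' @param verbose Emit progress messages.
#' @return A list of class `personalized_panel_set`: `panels` (named list,
#'   subject -> genes x cell-types matrix), `gene_ids`, `cell_types`, `fits`
#'   (named list of `gene_lmm_fit`).
#' @export
run_stage2 <- function(bulk, theta, genes = NULL, covariates = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(bulk, "bulk_experiment"))
  theta <- as.matrix(theta)
  if (!identical(rownames(theta), colnames(bulk$expression)))
    theta <- theta[colnames(bulk$expression), , drop = FALSE]
  tab <- table(bulk$samples$subject_id)
  if (any(tab < 2))
    stop("repeated measures are required: subject(s) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "),
         ". Stage II needs >= 2 samples per subject.")
  if (is.null(genes)) genes <- rownames(bulk$expression)
  missing_genes <- setdiff(genes, rownames(bulk$expression))
  if (length(missing_genes))
    stop("gene(s) not in bulk: ", paste(head(missing_genes, 5), collapse = ", "))
  subject <- bulk$samples$subject_id
  grp <- subject_groups(bulk)
  pd_msg(verbose, sprintf(
    "stage 2: fitting %d gene-wise mixed models (%d subjects, %d samples)",
    length(genes), length(grp), ncol(bulk$expression)))

  fits <- lapply(genes, function(g)
    fit_gene_lmm(bulk$expression[g, ], theta, subject, grp, covariates))
  names(fits) <- genes

  subjects <- names(grp)
  cell_types <- colnames(theta)
  panels <- lapply(subjects, function(s) {
    m <- t(vapply(fits, assemble_subject_panel, numeric(length(cell_types)),
                  subject = s, z = grp[[s]]))
    dimnames(m) <- list(genes, cell_types)
    m
  })
  names(panels) <- subjects
  n_fb <- sum(vapply(fits, function(f) f$fallback != "none", logical(1)))
  pd_msg(verbose, sprintf(
    "stage 2: assembled %d personalized panels (%d x %d); %d OLS fallback(s)",
    length(panels), length(genes), length(cell_types), n_fb))
  structure(list(panels = panels, gene_ids = genes, cell_types = cell_types,
                 fits = fits),
            class = "personalized_panel_set")
}

#' @export
print.personalized_panel_set <- function(x, ...) {
  cat(sprintf("personalized_panel_set: %d subjects, %d genes x %d cell types\n",
              length(x$panels), length(x$gene_ids), length(x$cell_types)))
  if (!is.null(x$fits)) {
    n_fb <- sum(vapply(x$fits, function(f) f$fallback != "none", logical(1)))
    cat(sprintf("  gene-wise REML fits: %d (%d OLS fallback)\n",
                length(x$fits), n_fb))
  }
  invisible(x)
}
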