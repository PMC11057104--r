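#' Personalized cell-type deconvolution of repeated-measures bulk RNA-seq
#'
#' Fits the full three-stage personalized deconvolution model. Stage I
#' deconvolves every sample against the population signature matrix by linear
#' nu-support-vector regression ([run_stage1()]). Stage II fits, for each
#' marker gene, a linear mixed-effect model of expression on the Stage I
#' proportions — fixed cell-type means, fixed case-control differences, and
#' subject-level random slopes — and assembles a personalized reference panel
#' per subject ([run_stage2()]). Stage III re-deconvolves each subject's
#' repeats against their own panel by non-negative least squares, or
#' sample-wise nu-SVR ([run_stage3()]).
#'
#' The linear mixing model lives in linear (not log) expression space; raw
#' counts are therefore scaled to counts-per-million per sample before Stage I
#' unless `normalize = FALSE` (pass pre-normalized expression in that case).
#'
#' @param bulk A [bulk_experiment()], or a genes x samples matrix (then
#'   `metadata` is required).
#' @param signature A [signature_matrix()] (marker genes x cell types), or a
#'   plain matrix coerced through [signature_matrix()].
#' @param metadata Sample metadata data frame (see [bulk_experiment()]) when
#'   `bulk` is a matrix.
#' @param normalize Scale each sample to counts-per-million before fitting
#'   (default `TRUE`).
#' @param solver Stage III solver, `"nnls"` (default) or `"svr"`.
#' @param genes `"signature"` (default) fits Stage II on the signature's
#'   marker genes; `"all"` fits every gene in the bulk (slower; panels then
#'   cover the genome but Stage III still deconvolves over the marker genes
#'   present in the panels).
#' @param covariates Optional samples x covariates numeric matrix passed to
#'   Stage II as extra fixed-effect interactions.
#' @param control An [svr_control()] for the SVR fits.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `persdecon` with components `proportions` (the
#'   Stage III [proportion_set()]), `stage1` (the coarse [proportion_set()]),
#'   `panels` (the `personalized_panel_set`), `bulk` (validated, normalized
#'   as fitted), `signature`, `solver`, `genes`, `normalize`, `call`. Use
#'   [coef.persdecon()], [fitted.persdecon()], [residuals.persdecon()],
#'   [predict.persdecon()], [plot.persdecon()].
#' @examples
#' sim <- simulate_deconv_data(sim_config(n_genes = 80, n_celltypes = 3,
#'   n_subjects_per_group = 4, n_markers = 40, alpha_ctrl = c(6, 3, 1),
#'   alpha_case = c(5, 4, 1), mvn_mean_logmean = c(5, 4, 3),
#'   mvn_cov_logmean = diag(3), mvn_mean_logdisp = rep(log(0.1), 3),
#'   mvn_cov_logdisp = 0.25 * diag(3), de_celltypes = 1:2, seed = 11))
#' fit <- persdecon(sim$bulk, sim$signature)
#' fit
#' head(coef(fit))
#' @export
persdecon <- function(bulk, signature, metadata = NULL, normalize = TRUE,
                      solver = c("nnls", "svr"),
                      genes = c("signature", "all"), covariates = NULL,
                      control = svr_control(), verbose = FALSE) {
  solver <- match.arg(solver)
  genes <- match.arg(genes)
  cl <- match.call()
  if (!inherits(bulk, "bulk_experiment")) {
    if (is.null(metadata))
      stop("metadata is required when bulk is a plain matrix")
    bulk <- bulk_experiment(bulk, metadata)
  }
  if (!inherits(signature, "signature_matrix"))
    signature <- signature_matrix(signature)

  if (normalize) {
    pd_msg(verbose, "normalizing samples to counts-per-million")
    bulk$expression <- cpm(bulk$expression)
  }

  stage1 <- run_stage1(bulk, signature, control, verbose = verbose)

  fit_genes <- if (genes == "signature")
    intersect(rownames(signature), rownames(bulk$expression))
  else rownames(bulk$expression)
  panels <- run_stage2(bulk, stage1, genes = fit_genes,
                       covariates = covariates, verbose = verbose)

  proportions <- run_stage3(bulk, panels, solver = solver, control = control,
                            verbose = verbose)

  structure(list(proportions = proportions, stage1 = stage1, panels = panels,
                 bulk = bulk, signature = signature, solver = solver,
                 genes = genes, normalize = normalize, control = control,
                 call = cl),
            class = "persdecon")
}

#' @export
print.persdecon <- function(x, ...) {
  cat("Personalized cell-type deconvolution (3-stage fit)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("  %d samples, %d subjects, %d cell types; stage III solver: %s\n",
              nrow(x$proportions), length(x$panels$panels),
              ncol(x$proportions), x$solver))
  cat(sprintf("  personalized panels over %d genes\n",
              length(x$panels$gene_ids)))
  cat("mean estimated proportions:\n")
  print(round(colMeans(x$proportions), 4))
  invisible(x)
}

#' Extract estimated cell-type proportions
#'
#' @param object A `persdecon` fit.
#' @param stage `"stage3"` (default, the personalized estimate) or `"stage1"`
#'   (the coarse population-reference estimate).
#' @param ... Unused.
#' @return A [proportion_set()] (samples x cell types).
#' @export
coef.persdecon <- function(object, stage = c("stage3", "stage1"), ...) {
  stage <- match.arg(stage)
  if (stage == "stage3") object$proportions else object$stage1
}

#' Reconstructed expression under the fitted mixture
#'
#' For each sample, the product of its subject's personalized panel with the
#' sample's raw-scale Stage III abundances: the model's reconstruction of the
#' (normalized) expression over the panel genes.
#'
#' @param object A `persdecon` fit.
#' @param ... Unused.
#' @return Genes x samples matrix.
#' @export
fitted.persdecon <- function(object, ...) {
  raw <- attr(object$proportions, "raw")
  if (is.null(raw)) raw <- unclass(object$proportions)
  genes <- intersect(object$panels$gene_ids, rownames(object$bulk$expression))
  out <- matrix(NA_real_, length(genes), nrow(raw),
                dimnames = list(genes, rownames(raw)))
  for (s in names(object$panels$panels)) {
    smp <- object$bulk$samples$sample_id[object$bulk$samples$subject_id == s]
    out[, smp] <- object$panels$panels[[s]][genes, , drop = FALSE] %*%
      t(raw[smp, , drop = FALSE])
  }
  out
}

#' Residuals of the fitted mixture
#'
#' Observed (normalized) expression minus [fitted.persdecon()], over the
#' panel genes.
#'
#' @param object A `persdecon` fit.
#' @param ... Unused.
#' @return Genes x samples matrix.
#' @export
residuals.persdecon <- function(object, ...) {
  f <- fitted(object)
  object$bulk$expression[rownames(f), colnames(f)] - f
}

#' @export
summary.persdecon <- function(object, ...) {
  fits <- object$panels$fits
  n_fb <- if (is.null(fits)) NA_integer_
          else sum(vapply(fits, function(f) f$fallback != "none", logical(1)))
  shift <- colMeans(object$proportions) - colMeans(object$stage1)
  r <- residuals(object)
  structure(list(call = object$call,
                 n_samples = nrow(object$proportions),
                 n_subjects = length(object$panels$panels),
                 n_genes = length(object$panels$gene_ids),
                 cell_types = colnames(object$proportions),
                 solver = object$solver,
                 mean_stage1 = colMeans(object$stage1),
                 mean_stage3 = colMeans(object$proportions),
                 shift = shift, n_fallback = n_fb,
                 resid_rms = sqrt(mean(r^2))),
            class = "summary.persdecon")
}

#' @export
print.summary.persdecon <- function(x, ...) {
  cat("Personalized cell-type deconvolution\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d samples from %d subjects; %d panel genes; solver %s\n",
              x$n_samples, x$n_subjects, x$n_genes, x$solver))
  tab <- rbind(`stage 1 (population ref)` = x$mean_stage1,
               `stage 3 (personalized)` = x$mean_stage3,
               shift = x$shift)
  print(round(tab, 4))
  if (!is.na(x$n_fallback))
    cat(sprintf("gene models falling back to OLS: %d/%d\n",
                x$n_fallback, x$n_genes))
  cat(sprintf("root-mean-square reconstruction residual: %.4g\n", x$resid_rms))
  invisible(x)
}

#' Deconvolve new samples of already-fitted subjects
#'
#' Applies the fitted personalized panels to new repeated measures of the
#' same subjects (e.g. a later visit), without refitting Stages I-II.
#'
#' @param object A `persdecon` fit.
#' @param newdata A [bulk_experiment()] (or matrix plus `metadata`) whose
#'   subjects all have fitted panels.
#' @param metadata Metadata data frame when `newdata` is a matrix.
#' @param ... Unused.
#' @return A [proportion_set()] with origin `"stage3"`.
#' @export
predict.persdecon <- function(object, newdata, metadata = NULL, ...) {
  if (!inherits(newdata, "bulk_experiment"))
    newdata <- bulk_experiment(newdata, metadata)
  if (object$normalize) newdata$expression <- cpm(newdata$expression)
  run_stage3(newdata, object$panels, solver = object$solver,
             control = object$control)
}

#' Diagnostic plot of a personalized deconvolution fit
#'
#' Scatter of the Stage III personalized estimates against the Stage I coarse
#' estimates, one panel colour per cell type, with the diagonal as reference;
#' points off the diagonal show where the personalized panels revised the
#' composition. If `truth` is supplied, both estimates are plotted against
#' the truth instead.
#'
#' @param x A `persdecon` fit.
#' @param truth Optional samples x cell-types truth matrix.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.persdecon <- function(x, truth = NULL, ...) {
  K <- ncol(x$proportions)
  cols <- grDevices::hcl.colors(K, "Dark 3")
  if (is.null(truth)) {
    graphics::plot(as.vector(unclass(x$stage1)),
                   as.vector(unclass(x$proportions)),
                   col = rep(cols, each = nrow(x$proportions)),
                   xlab = "stage I proportion (population reference)",
                   ylab = "stage III proportion (personalized)",
                   pch = 16, cex = 0.6, ...)
  } else {
    truth <- as.matrix(truth)[rownames(x$proportions), , drop = FALSE]
    graphics::plot(as.vector(truth), as.vector(unclass(x$proportions)),
                   col = rep(cols, each = nrow(x$proportions)),
                   xlab = "true proportion",
                   ylab = "estimated proportion (personalized)",
                   pch = 16, cex = 0.6, ...)
    graphics::points(as.vector(truth), as.vector(unclass(x$stage1)),
                     col = "grey60", pch = 1, cex = 0.5)
    graphics::legend("topleft", legend = c("personalized", "population ref"),
                     col = c(cols[1], "grey60"), pch = c(16, 1), bty = "n")
  }
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
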