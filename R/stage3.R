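#' Jointly deconvolve one subject's repeats against their personalized panel
#'
#' Solves, for subject *n* with panel \eqn{R_n} and expression matrix
#' \eqn{y_n} (genes x repeats), the non-negative least-squares problem
#' \deqn{\min_{\Theta \ge 0} \| (R_n \otimes I_{t_n})\,vec(\Theta') - vec(y_n') \|_2.}
#' The Kronecker system couples no entries across repeats, so it is solved as
#' independent per-repeat active-set NNLS fits — mathematically identical to
#' the joint vectorized problem (an equivalence exercised in the test suite)
#' at a fraction of the cost.
#'
#' @param y_n Genes x repeats expression matrix for one subject (a single
#'   vector is treated as one repeat).
#' @param R_n Genes x cell-types personalized reference panel, same gene
#'   order.
#' @return Cell-types x repeats matrix of non-negative abundances (raw scale,
#'   not normalized).
#' @export
deconvolve_subject_nnls <- function(y_n, R_n) {
  y_n <- as.matrix(y_n)
  R_n <- as.matrix(R_n)
  if (nrow(y_n) != nrow(R_n))
    stop("y_n and R_n must share gene ordering (row counts differ)")
  zero_col <- colSums(R_n != 0) == 0
  if (any(zero_col))
    warning("all-zero panel column(s); abundance fixed at 0 for: ",
            paste(colnames(R_n)[zero_col], collapse = ", "))
  use <- which(!zero_col)
  theta <- matrix(0, ncol(R_n), ncol(y_n),
                  dimnames = list(colnames(R_n), colnames(y_n)))
  for (i in seq_len(ncol(y_n))) {
    theta[use, i] <- pracma::lsqnonneg(R_n[, use, drop = FALSE], y_n[, i])$x
  }
  theta
}

#' Stage III: personalized deconvolution of all subjects
#'
#' Re-deconvolves every sample against its subject's personalized reference
#' panel from Stage II, either by joint non-negative least squares per subject
#' (`solver = "nnls"`, the default) or by routing each sample through the
#' Stage I nu-SVR machinery with the personalized panel in place of the
#' population signature (`solver = "svr"`).
#'
#' The NNLS objective constrains the abundances only to be non-negative; since
#' downstream evaluation treats them as proportions, rows are normalized to
#' sum to one by default (`normalize_output`). All-zero rows become uniform
#' with a warning. The raw-scale solution is attached as attribute `raw`.
#'
#' @param bulk A [bulk_experiment()] on the same expression scale as the
#'   panels.
#' @param panels A `personalized_panel_set` from [run_stage2()] covering every
#'   subject in `bulk`.
#' @param solver `"nnls"` or `"svr"`.
#' @param control [svr_control()] used when `solver = "svr"`.
#' @param normalize_output Normalize rows to the simplex (default `TRUE`).
#' @param verbose Emit progress messages.
#' @return A [proportion_set()] with origin `"stage3"` (when
#'   `normalize_output = FALSE`, a plain samples x cell-types matrix).
#' @export
run_stage3 <- function(bulk, panels, solver = c("nnls", "svr"),
                       control = svr_control(), normalize_output = TRUE,
                       verbose = FALSE) {
  solver <- match.arg(solver)
  stopifnot(inherits(bulk, "bulk_experiment"),
            inherits(panels, "personalized_panel_set"))
  subjects <- unique(bulk$samples$subject_id)
  missing_panel <- setdiff(subjects, names(panels$panels))
  if (length(missing_panel))
    stop("no personalized panel for subject(s): ",
         paste(missing_panel, collapse = ", "))
  genes <- intersect(panels$gene_ids, rownames(bulk$expression))
  if (length(genes) < length(panels$cell_types))
    stop("fewer shared genes than cell types between bulk and panels")

  K <- length(panels$cell_types)
  out <- matrix(NA_real_, ncol(bulk$expression), K,
                dimnames = list(colnames(bulk$expression), panels$cell_types))
  for (s in subjects) {
    R_n <- panels$panels[[s]][genes, , drop = FALSE]
    smp <- bulk$samples$sample_id[bulk$samples$subject_id == s]
    Y_n <- bulk$expression[genes, smp, drop = FALSE]
    if (solver == "nnls") {
      out[smp, ] <- t(deconvolve_subject_nnls(Y_n, R_n))
    } else {
      for (i in smp)
        out[i, ] <- pmax(deconvolve_sample_svr(Y_n[, i], R_n, control), 0)
    }
  }
  pd_msg(verbose, sprintf(
    "stage 3 (%s): deconvolved %d samples against %d personalized panels over %d genes",
    solver, nrow(out), length(subjects), length(genes)))
  raw <- out
  if (!normalize_output) return(out)
  rs <- rowSums(out)
  zero <- rs == 0
  if (any(zero)) {
    warning("all-zero abundance row(s) set to uniform: ",
            paste(rownames(out)[zero], collapse = ", "))
    out[zero, ] <- 1 / K
    rs[zero] <- 1
  }
  p <- proportion_set(out / rs, "stage3")
  attr(p, "raw") <- raw
  p
}
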