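# Evaluation metrics for compositional deconvolution accuracy. All operate on
# samples x cell-types matrices with matching shapes; "candidate" vs
# "baseline" estimates are compared against the ground truth.

# internal: shape check
check_aligned <- function(...) {
  ms <- list(...)
  d <- dim(ms[[1]])
  for (m in ms[-1])
    if (!identical(dim(m), d))
      stop("proportion matrices must share sample and cell-type dimensions")
  invisible(NULL)
}

#' Absolute bias difference (ABD) and its relative variant (rABD)
#'
#' `abd()` is the difference in total absolute estimation error between a
#' candidate and a baseline estimate:
#' \deqn{ABD = \sum |\hat\Theta_{cand} - \Theta| - \sum |\hat\Theta_{base} - \Theta|,}
#' negative when the candidate is more accurate. `rabd()` replaces the totals
#' by mean relative absolute errors \eqn{|\hat\Theta - \Theta| / \Theta} and
#' reports the difference in percent; truth entries at or below `guard` are
#' excluded from the average (the relative error is undefined at zero truth)
#' and their count is reported as attribute `n_excluded`.
#'
#' @param candidate,baseline,truth Samples x cell-types proportion matrices
#'   with identical shapes.
#' @param guard Truth entries `<= guard` are skipped by `rabd()`.
#' @return A single number (`rabd()` is in percent).
#' @export
abd <- function(candidate, baseline, truth) {
  candidate <- as.matrix(candidate); baseline <- as.matrix(baseline)
  truth <- as.matrix(truth)
  check_aligned(candidate, baseline, truth)
  sum(abs(candidate - truth)) - sum(abs(baseline - truth))
}

#' @rdname abd
#' @export
rabd <- function(candidate, baseline, truth, guard = 1e-6) {
  candidate <- as.matrix(candidate); baseline <- as.matrix(baseline)
  truth <- as.matrix(truth)
  check_aligned(candidate, baseline, truth)
  keep <- truth > guard
  out <- (mean(abs(candidate[keep] - truth[keep]) / truth[keep]) -
          mean(abs(baseline[keep] - truth[keep]) / truth[keep])) * 100
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Correlation difference (CD)
#'
#' Difference in Pearson correlation with the truth, computed over all
#' flattened (sample, cell-type) entries:
#' \deqn{CD = corr(\hat\Theta_{cand}, \Theta) - corr(\hat\Theta_{base}, \Theta).}
#' Positive values mean the candidate tracks the truth better.
#'
#' @inheritParams abd
#' @return A single number in [-2, 2].
#' @export
cd <- function(candidate, baseline, truth) {
  candidate <- as.matrix(candidate); baseline <- as.matrix(baseline)
  truth <- as.matrix(truth)
  check_aligned(candidate, baseline, truth)
  if (sd(as.vector(candidate)) == 0 || sd(as.vector(baseline)) == 0 ||
      sd(as.vector(truth)) == 0)
    stop("zero-variance input; correlation undefined")
  cor(as.vector(candidate), as.vector(truth)) -
    cor(as.vector(baseline), as.vector(truth))
}

#' Per-cell-type Pearson correlation with the truth
#'
#' Companion to [cd()] for per-cell-type reporting.
#'
#' @param estimate,truth Matched samples x cell-types matrices.
#' @return Named vector of per-column correlations.
#' @export
celltype_correlations <- function(estimate, truth) {
  estimate <- as.matrix(estimate); truth <- as.matrix(truth)
  check_aligned(estimate, truth)
  setNames(vapply(seq_len(ncol(truth)),
                  function(k) cor(estimate[, k], truth[, k]), numeric(1)),
           colnames(truth))
}

#' Lin's concordance correlation coefficient and variants
#'
#' `lin_ccc()` measures agreement between two matched measurements as
#' \deqn{\rho_C = 1 - E[(x - y)^2] / E_I[(x - y)^2],}
#' where the denominator is the expected squared difference if `x` and `y`
#' were independent with the same marginals: \eqn{\sigma_x^2 + \sigma_y^2 +
#' (\mu_x - \mu_y)^2} (population moments). It equals Lin's classical
#' closed form \eqn{2\,s_{xy} / (s_x^2 + s_y^2 + (\mu_x-\mu_y)^2)} and is
#' bounded by 1 (perfect agreement) and -1. Computed over all flattened
#' entries.
#'
#' `lin_ccc_euclidean()` is the per-sample Euclidean variant: the numerator is
#' the mean over samples of the squared Euclidean distance between the two
#' composition vectors, and the denominator sums the componentwise
#' independence terms over the K cell types.
#'
#' `lin_ccc_aitchison()` applies the Euclidean construction to
#' centered-log-ratio-transformed compositions (the Aitchison geometry): each
#' row gets a pseudocount, is re-closed, log-transformed and row-centred. An
#' approximate, documented stand-in for a fully compositional concordance
#' measure.
#'
#' @param x,y Matched samples x cell-types matrices (any matched numeric
#'   matrices for `lin_ccc()`).
#' @param pseudocount Added to every entry before closure in
#'   `lin_ccc_aitchison()`.
#' @return A single number in [-1, 1].
#' @export
lin_ccc <- function(x, y) {
  x <- as.vector(as.matrix(x)); y <- as.vector(as.matrix(y))
  if (length(x) != length(y)) stop("x and y must have matching shapes")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  den <- vx + vy + (mx - my)^2
  if (den <= 0)
    stop("degenerate input: zero variance and equal means")
  1 - mean((x - y)^2) / den
}

#' @rdname lin_ccc
#' @export
lin_ccc_euclidean <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  check_aligned(x, y)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colMeans(sweep(x, 2, mx)^2); vy <- colMeans(sweep(y, 2, my)^2)
  den <- sum(vx + vy + (mx - my)^2)
  if (den <= 0)
    stop("degenerate input: zero variance and equal means")
  num <- mean(rowSums((x - y)^2))
  1 - num / den
}

#' @rdname lin_ccc
#' @export
lin_ccc_aitchison <- function(x, y, pseudocount = 1e-6) {
  lin_ccc_euclidean(clr_transform(x, pseudocount),
                    clr_transform(y, pseudocount))
}

# internal: pseudocount + closure + centered log-ratio per row
clr_transform <- function(m, pseudocount) {
  m <- as.matrix(m) + pseudocount
  m <- m / rowSums(m)
  lm_ <- log(m)
  lm_ - rowMeans(lm_)
}

#' Full metric report for a candidate/baseline pair against the truth
#'
#' Computes every evaluation metric in one pass: [abd()], [rabd()], [cd()],
#' Lin's concordance of each estimate with the truth ([lin_ccc()]), the
#' Euclidean variant ([lin_ccc_euclidean()]), their candidate-minus-baseline
#' differences, the percentage improvement of the Euclidean concordance
#' relative to the baseline, and (optionally) the Aitchison variant pair.
#'
#' @param candidate,baseline,truth Matched samples x cell-types proportion
#'   matrices (candidate = personalized Stage III estimate, baseline =
#'   population-reference Stage I estimate).
#' @param aitchison Include the Aitchison-variant pair.
#' @return A list of class `metric_report` with fields `abd`, `rabd_percent`,
#'   `cd`, `ccc_candidate`, `ccc_baseline`, `delta_ccc`, `ccc_e_candidate`,
#'   `ccc_e_baseline`, `delta_ccc_e`, `delta_ccc_e_percent`,
#'   `ccc_a_candidate`, `ccc_a_baseline`, and `celltype_cor` (per-cell-type
#'   correlation of each estimate with the truth).
#' @export
evaluate_pair <- function(candidate, baseline, truth, aitchison = TRUE) {
  candidate <- as.matrix(candidate); baseline <- as.matrix(baseline)
  truth <- as.matrix(truth)
  check_aligned(candidate, baseline, truth)
  ccc_c <- lin_ccc(truth, candidate)
  ccc_b <- lin_ccc(truth, baseline)
  ccc_e_c <- lin_ccc_euclidean(truth, candidate)
  ccc_e_b <- lin_ccc_euclidean(truth, baseline)
  rep <- list(
    abd = abd(candidate, baseline, truth),
    rabd_percent = as.numeric(rabd(candidate, baseline, truth)),
    cd = cd(candidate, baseline, truth),
    ccc_candidate = ccc_c, ccc_baseline = ccc_b,
    delta_ccc = ccc_c - ccc_b,
    ccc_e_candidate = ccc_e_c, ccc_e_baseline = ccc_e_b,
    delta_ccc_e = ccc_e_c - ccc_e_b,
    delta_ccc_e_percent = (ccc_e_c - ccc_e_b) / ccc_e_b * 100,
    celltype_cor = rbind(candidate = celltype_correlations(candidate, truth),
                         baseline = celltype_correlations(baseline, truth))
  )
  if (aitchison) {
    rep$ccc_a_candidate <- lin_ccc_aitchison(truth, candidate)
    rep$ccc_a_baseline <- lin_ccc_aitchison(truth, baseline)
  }
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("deconvolution accuracy, candidate vs baseline (negative ABD/rABD and\n")
  cat("positive CD/delta-CCC mean the candidate improves on the baseline):\n")
  f <- function(v) formatC(v, digits = digits, format = "g")
  cat(sprintf("  ABD   %s    rABD   %s%%\n", f(x$abd), f(x$rabd_percent)))
  cat(sprintf("  CD    %s\n", f(x$cd)))
  cat(sprintf("  Lin CCC        %s vs %s  (delta %s)\n",
              f(x$ccc_candidate), f(x$ccc_baseline), f(x$delta_ccc)))
  cat(sprintf("  Euclidean CCC  %s vs %s  (delta %s, %s%%)\n",
              f(x$ccc_e_candidate), f(x$ccc_e_baseline), f(x$delta_ccc_e),
              f(x$delta_ccc_e_percent)))
  if (!is.null(x$ccc_a_candidate))
    cat(sprintf("  Aitchison CCC  %s vs %s\n",
                f(x$ccc_a_candidate), f(x$ccc_a_baseline)))
  invisible(x)
}

#' Write a metric report to TSV
#'
#' Writes the scalar metrics as a one-row TSV at `path` and the per-cell-type
#' correlation table at `<path minus extension>_celltype.tsv`.
#'
#' @param report A `metric_report` from [evaluate_pair()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  scalars <- report[vapply(report, function(v)
    is.numeric(v) && length(v) == 1, logical(1))]
  write.table(as.data.frame(scalars), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ct_path <- paste0(tools::file_path_sans_ext(path), "_celltype.tsv")
  df <- data.frame(estimate = rownames(report$celltype_cor),
                   report$celltype_cor, check.names = FALSE)
  write.table(df, ct_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
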