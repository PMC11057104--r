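#' Control parameters for nu-SVR deconvolution
#'
#' Stage I (and the SVR variant of Stage III) regresses each sample's marker
#' expression on the signature columns with a linear nu-support-vector
#' regression. The nu parameter bounds the support-vector fraction; the fit is
#' repeated over `nu_grid` and the value minimizing the root-mean-square error
#' between the observed and reconstructed expression is kept (smallest nu wins
#' exact ties).
#'
#' @param nu_grid Numeric vector of nu values in (0, 1].
#' @param cost Positive regularization constant C of the epsilon-insensitive
#'   loss.
#' @param standardize If `TRUE` (default) the response and each signature
#'   column are z-scored over the shared marker genes before fitting and the
#'   coefficients are mapped back to the expression scale afterwards. This
#'   stabilizes the fit across expression scales and makes the normalized
#'   output invariant to rescaling of the sample.
#' @return A list of class `svr_control`.
#' @export
svr_control <- function(nu_grid = c(0.25, 0.5, 0.75), cost = 1,
                        standardize = TRUE) {
  if (!length(nu_grid) || any(nu_grid <= 0) || any(nu_grid > 1))
    stop("nu_grid must be non-empty with values in (0, 1]")
  if (cost <= 0) stop("cost must be positive")
  structure(list(nu_grid = sort(nu_grid), cost = cost,
                 standardize = isTRUE(standardize)),
            class = "svr_control")
}

#' Deconvolve one sample by linear nu-SVR
#'
#' Fits the linear mixing model y = E theta + b for a single sample by
#' nu-support-vector regression over the grid of nu values in `control`,
#' returning the raw coefficient vector of the best fit (coefficients may be
#' negative; see [truncate_and_normalize()] for the projection onto the
#' simplex).
#'
#' @param y Numeric vector of the sample's expression over the signature's
#'   marker genes (same order as `E` rows).
#' @param E Marker-genes x cell-types signature matrix.
#' @param control An [svr_control()].
#' @return Numeric vector of length K (cell types) of raw regression
#'   coefficients, with attributes `nu` (selected grid value) and `rmse`.
#' @export
deconvolve_sample_svr <- function(y, E, control = svr_control()) {
  E <- as.matrix(E)
  if (length(y) != nrow(E))
    stop("length(y) must equal nrow(E)")
  if (nrow(E) < ncol(E))
    stop(sprintf("need at least %d shared marker genes, got %d",
                 ncol(E), nrow(E)))
  if (sd(y) == 0)
    stop("sample has zero variance across marker genes; cannot deconvolve")

  if (control$standardize) {
    mu_y <- mean(y); sd_y <- sd(y)
    sd_E <- apply(E, 2, sd)
    sd_E[sd_E == 0] <- 1
    ys <- (y - mu_y) / sd_y
    Es <- scale(E, center = TRUE, scale = sd_E)
  } else {
    ys <- y; Es <- E
    sd_y <- 1; sd_E <- rep(1, ncol(E))
  }

  best <- NULL
  for (nu in control$nu_grid) {
    fit <- e1071::svm(Es, ys, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = control$cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))           # weights, standardized space
    theta <- w * sd_y / sd_E                          # back to expression scale
    yhat <- drop(E %*% theta)
    b <- mean(y - yhat)                               # free intercept
    rmse <- sqrt(mean((y - yhat - b)^2))
    if (is.null(best) || rmse < best$rmse)            # strict <: ties keep smaller nu
      best <- list(theta = theta, nu = nu, rmse = rmse)
  }
  structure(setNames(best$theta, colnames(E)), nu = best$nu,
            rmse = best$rmse)
}

#' Project raw deconvolution coefficients onto the simplex
#'
#' Negative coefficients are set to zero and the remainder rescaled to sum to
#' one. If no coefficient is positive the uniform composition is returned with
#' a warning.
#'
#' @param raw Numeric coefficient vector (one entry per cell type).
#' @return Non-negative vector summing to one.
#' @examples
#' truncate_and_normalize(c(-0.1, 0.6, 0.5))  # (0, 6/11, 5/11)
#' @export
truncate_and_normalize <- function(raw) {
  out <- pmax(as.numeric(raw), 0)
  names(out) <- names(raw)
  s <- sum(out)
  if (s <= 0) {
    warning("all deconvolution coefficients non-positive; returning uniform")
    return(setNames(rep(1 / length(out), length(out)), names(out)))
  }
  out / s
}

#' Stage I: coarse deconvolution of every sample
#'
#' Runs [deconvolve_sample_svr()] followed by [truncate_and_normalize()] for
#' each sample of a bulk experiment against the population signature matrix,
#' over the marker genes the two share.
#'
#' @param bulk A [bulk_experiment()]. Expression should already be on the
#'   scale the signature lives on (the [persdecon()] driver CPM-normalizes
#'   counts first).
#' @param signature A [signature_matrix()].
#' @param control An [svr_control()].
#' @param verbose Emit progress messages.
#' @return A [proportion_set()] with origin `"stage1"`, one row per sample.
#' @export
run_stage1 <- function(bulk, signature, control = svr_control(),
                       verbose = FALSE) {
  stopifnot(inherits(bulk, "bulk_experiment"))
  shared <- intersect(rownames(signature), rownames(bulk$expression))
  K <- ncol(signature)
  lost <- nrow(signature) - length(shared)
  pd_msg(verbose, sprintf(
    "stage 1: %d/%d signature genes found in bulk (%d dropped)",
    length(shared), nrow(signature), lost))
  if (lost > 0.5 * nrow(signature))
    warning(sprintf("more than half of the signature genes (%d/%d) are absent from the bulk data",
                    lost, nrow(signature)))
  if (length(shared) < K)
    stop(sprintf("only %d genes shared between bulk and signature; need at least K = %d",
                 length(shared), K))
  E <- signature[shared, , drop = FALSE]
  Y <- bulk$expression[shared, , drop = FALSE]
  theta <- t(apply(Y, 2, function(y)
    truncate_and_normalize(deconvolve_sample_svr(y, E, control))))
  dimnames(theta) <- list(colnames(Y), colnames(E))
  pd_msg(verbose, sprintf("stage 1: deconvolved %d samples into %d cell types",
                          nrow(theta), K))
  proportion_set(theta, "stage1")
}
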