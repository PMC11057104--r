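# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

# small bulk experiment with known structure
make_bulk <- function(G = 6, subjects = c("a", "b"), repeats = 2,
                      seed = 42, counts = NULL) {
  set.seed(seed)
  samples <- as.vector(outer(subjects, seq_len(repeats), paste, sep = "_r"))
  md <- data.frame(
    sample_id = samples,
    subject_id = rep(subjects, times = repeats),
    repeat_index = rep(seq_len(repeats), each = length(subjects)),
    group = rep(as.integer(seq_along(subjects) %% 2 == 0), times = repeats)
  )
  if (is.null(counts))
    counts <- matrix(rpois(G * length(samples), 60), G, length(samples))
  dimnames(counts) <- list(paste0("g", seq_len(G)), samples)
  bulk_experiment(counts, md)
}

# well-conditioned signature with cell-type-exclusive marker blocks
make_signature <- function(J = 60, K = 3, seed = 7, specificity = 20) {
  set.seed(seed)
  E <- matrix(runif(J * K, 1, 5), J, K)
  block <- split(seq_len(J), rep(seq_len(K), length.out = J))
  for (k in seq_len(K)) E[block[[k]], k] <- E[block[[k]], k] * specificity
  dimnames(E) <- list(paste0("g", seq_len(J)), paste0("ct", seq_len(K)))
  signature_matrix(E)
}

# random compositions via Dirichlet
rdirichlet_mat <- function(n, alpha) {
  m <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(length(alpha), alpha)
    g / sum(g)
  }, numeric(length(alpha))))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("ct", seq_along(alpha)))
  m
}

# small simulation config used across tests (kept light: G=150, N=6/group)
small_sim_config <- function(seed = 5, ...) {
  args <- list(...)
  defaults <- list(n_genes = 150, n_celltypes = 3, n_subjects_per_group = 6,
                   repeats_per_subject = 3, n_markers = 75,
                   de_celltypes = 1:2,
                   mvn_mean_logmean = c(5, 4, 3),
                   mvn_cov_logmean = equicor3(1, 0.8),
                   mvn_mean_logdisp = rep(log(0.15), 3),
                   mvn_cov_logdisp = equicor3(0.5, 0.5),
                   alpha_ctrl = c(8, 5, 2), alpha_case = c(7, 6, 2),
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

equicor3 <- function(sd, rho) {
  S <- matrix(rho, 3, 3); diag(S) <- 1
  S * sd^2
}
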