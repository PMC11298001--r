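#' Default parameters for the archetype cohort simulator
#'
#' Builds a self-contained parameterization of the cohort generator: each
#' sample's cell-state space is spanned by `K_arch` archetypes; the
#' archetype expression of each gene responds linearly to sample-level
#' covariates through sparse planted effect matrices `X_g` (the
#' ground-truth differential expression), on top of a fixed per-gene
#' baseline profile; per-sample archetype variability follows a
#' low-rank-plus-diagonal covariance; cells are Dirichlet-concentrated
#' convex combinations of their sample's archetypes, with log-normal
#' sequencing depths.
#'
#' Covariate 1 is a balanced binary condition (half the samples 0, half
#' 1); any further covariates are standard normal draws per sample.
#' Effects are in `log2` units (`log_base = 2`), so thresholds on the
#' ground-truth DE values are log2 fold changes.
#'
#' @param G,N,Q number of genes, cells, samples.
#' @param K_arch number of archetypes.
#' @param L number of sample-level covariates.
#' @param seed integer seed; the whole parameter set is a deterministic
#'   function of it.
#' @param effect_fraction fraction of genes with planted covariate effects.
#' @param effect_sd SD of nonzero effect entries (log2 units).
#' @param baseline_sd SD of per-gene baseline log2 expression.
#' @param archetype_sd SD of per-archetype baseline deviations (the
#'   cell-type structure).
#' @param global_sd SD of the global per-gene artifact row `x'_g`
#'   (default 0; set > 0 to stress ambient-RNA-like confounding).
#' @param tau,omega low-rank and diagonal scales of the per-gene
#'   archetype covariance `Sigma_g = tau^2 u u' + omega^2 I`.
#' @param sigma_range range of the uniform per-gene cell-level SD.
#' @param depth_meanlog,depth_sdlog log-normal depth parameters.
#' @param alpha_dominant,alpha_other Dirichlet concentrations for the
#'   dominant and remaining archetype weights of each cell.
#' @param log_base logarithm base `c` of the latent profiles.
#' @return object of class `gedi_sim_params`.
#' @export
sim_params <- function(G = 300, N = 2000, Q = 12, K_arch = 5, L = 2,
                       seed = 1, effect_fraction = 0.2, effect_sd = 1,
                       baseline_sd = 1.5, archetype_sd = 1, global_sd = 0,
                       tau = 0.3, omega = 0.2, sigma_range = c(0.2, 0.5),
                       depth_meanlog = log(2000), depth_sdlog = 0.3,
                       alpha_dominant = 5, alpha_other = 0.5,
                       log_base = 2) {
  stopifnot(G >= 1, N >= 1, Q >= 1, K_arch >= 1, L >= 1, log_base > 1)
  set.seed(seed)
  ## sample covariates: balanced binary condition, then standard normals
  H <- matrix(0, L, Q, dimnames = list(paste0("h", seq_len(L)),
                                       paste0("sample", seq_len(Q))))
  H[1, ] <- rep(c(0, 1), length.out = Q)
  if (L > 1)
    H[-1, ] <- stats::rnorm((L - 1) * Q)
  rownames(H)[1] <- "condition"

  ## baseline archetype profiles (gene x archetype, no DE content)
  baseline <- matrix(stats::rnorm(G, 0, baseline_sd), G, K_arch) +
    matrix(stats::rnorm(G * K_arch, 0, archetype_sd), G, K_arch)

  ## sparse planted effects: X[k, l, g]
  de_gene <- stats::runif(G) < effect_fraction
  X <- array(0, dim = c(K_arch, L, G))
  n_de <- sum(de_gene)
  if (n_de > 0)
    X[, , de_gene] <- stats::rnorm(K_arch * L * n_de, 0, effect_sd)
  x_prime <- matrix(stats::rnorm(G * L, 0, global_sd), G, L)

  ## per-gene archetype covariance: low-rank + diagonal
  U <- matrix(stats::rnorm(G * K_arch), G, K_arch)
  U <- U / sqrt(rowSums(U^2))
  sigma_g <- stats::runif(G, sigma_range[1], sigma_range[2])

  ## cells: dominant archetype + Dirichlet weights; samples round-robin
  dominant <- sample.int(K_arch, N, replace = TRUE)
  alpha <- matrix(alpha_other, N, K_arch)
  alpha[cbind(seq_len(N), dominant)] <- alpha_dominant
  gam_draw <- matrix(stats::rgamma(N * K_arch, shape = alpha), N, K_arch)
  W <- gam_draw / rowSums(gam_draw)
  depths <- pmax(1, round(stats::rlnorm(N, depth_meanlog, depth_sdlog)))
  sample_map <- rep_len(seq_len(Q), N)

  structure(list(
    G = G, N = N, Q = Q, K_arch = K_arch, L = L, seed = seed,
    H = H, baseline = baseline, X = X, x_prime = x_prime,
    U = U, tau = tau, omega = omega, sigma_g = sigma_g,
    W = W, dominant = dominant, depths = depths,
    sample_map = sample_map, log_base = log_base,
    effect_fraction = effect_fraction, effect_sd = effect_sd
  ), class = "gedi_sim_params")
}

#' @export
print.gedi_sim_params <- function(x, ...) {
  cat(sprintf(paste0("gedi_sim_params: G=%d, N=%d, Q=%d, K_arch=%d, L=%d,",
                     " seed=%d\n"), x$G, x$N, x$Q, x$K_arch, x$L, x$seed))
  invisible(x)
}

#' Ground-truth differential expression of one cell
#'
#' The planted per-cell DE of the L covariates on every gene: row g of the
#' result is the row-vector \eqn{w_n X_g} (pure algebra on the simulation
#' parameters, no randomness).
#'
#' @param params a `gedi_sim_params`.
#' @param n cell index.
#' @return G x L matrix.
#' @export
truth_de <- function(params, n) {
  if (n < 1 || n > params$N) gedi_stop("cell index n out of range")
  w <- params$W[n, ]
  out <- t(apply(params$X, 3, function(Xg)
    w %*% matrix(Xg, params$K_arch, params$L)))
  if (params$L == 1) out <- matrix(out, ncol = 1)
  dimnames(out) <- list(paste0("g", seq_len(params$G)), rownames(params$H))
  out
}

## all cells at once, one G x N matrix per covariate
truth_de_all <- function(params) {
  lapply(seq_len(params$L), function(l) {
    M_l <- t(params$X[, l, , drop = TRUE])       # G x K_arch
    if (params$K_arch == 1) M_l <- matrix(params$X[, l, ], params$G, 1)
    D <- M_l %*% t(params$W)
    dimnames(D) <- list(paste0("g", seq_len(params$G)),
                        paste0("cell", seq_len(params$N)))
    D
  })
}

## latent log-expression field shared by both generators
simulate_latent <- function(params) {
  G <- params$G; N <- params$N; Q <- params$Q; K <- params$K_arch
  gamma <- array(0, dim = c(K, Q, G))
  Y <- matrix(0, G, N)
  t_W <- t(params$W)                               # K x N
  samp <- params$sample_map
  for (g in seq_len(G)) {
    X_g <- matrix(params$X[, , g], K, params$L)
    mean_g <- params$baseline[g, ] +
      X_g %*% params$H +
      rep(1, K) %*% (params$x_prime[g, ] %*% params$H)
    ## Sigma_g = tau^2 u u' + omega^2 I: draw as u * z0 * tau + omega * z
    z0 <- stats::rnorm(Q)
    noise <- params$tau * outer(params$U[g, ], z0) +
      params$omega * matrix(stats::rnorm(K * Q), K, Q)
    gam_g <- mean_g + noise
    gamma[, , g] <- gam_g
    Y[g, ] <- colSums(gam_g[, samp, drop = FALSE] * t_W) +
      stats::rnorm(N, 0, params$sigma_g[g])
  }
  list(gamma = gamma, Y = Y)
}

#' Simulate a cohort-level single-cell count dataset
#'
#' Draws archetype profiles per sample around their covariate-determined
#' means, latent per-cell log2 profiles as noisy convex combinations of
#' archetypes, and UMI counts by per-cell multinomial sampling of the
#' softmax-normalized latent profiles at the cell's depth. The planted
#' per-cell DE vectors (`w_n X_g`) are attached as ground truth.
#'
#' @param params a `gedi_sim_params`.
#' @param seed seed of the noise draws; defaults to `params$seed + 1`
#'   (offset so the noise stream differs from the parameter stream).
#'   Varying it with `params` fixed yields independent replicates of the
#'   same stated world.
#' @return object of class `gedi_sim_cohort`: list with `counts` (G x N
#'   integer matrix), `Y` (latent log2 profiles), `gamma` (K x Q x G
#'   archetype profiles), `truth` (list of L G x N ground-truth DE
#'   matrices), `sample_map`, `labels` (dominant-archetype surrogate cell
#'   types), and `params`.
#' @export
simulate_cohort <- function(params, seed = params$seed + 1L) {
  set.seed(seed)
  lat <- simulate_latent(params)
  logp <- lat$Y * log(params$log_base)
  logp <- sweep(logp, 2, apply(logp, 2, max), `-`)
  P <- exp(logp)
  P <- sweep(P, 2, colSums(P), `/`)
  counts <- matrix(0L, params$G, params$N)
  for (n in seq_len(params$N))
    counts[, n] <- stats::rmultinom(1, params$depths[n], P[, n])
  dimnames(counts) <- list(paste0("g", seq_len(params$G)),
                           paste0("cell", seq_len(params$N)))
  structure(list(
    counts = counts, Y = lat$Y, gamma = lat$gamma,
    truth = truth_de_all(params),
    sample_map = paste0("sample", params$sample_map),
    labels = paste0("arch", params$dominant),
    params = params
  ), class = "gedi_sim_cohort")
}

#' Default parameters for the paired-count (ratio modality) simulator
#'
#' Wraps [sim_params()] with defaults emulating cassette-exon splicing (or
#' spliced/unspliced) latent spaces: per-event mean logits vary widely
#' across events (`baseline_sd`), while the cross-cell variation of any
#' one event is subtle (cell-type-specific PSI shifts of a few percent,
#' `archetype_sd = 0.2`) and the unexplained cell-level noise is small.
#' At shallow per-event depths the binomial sampling noise of a naive
#' count-ratio estimate (logit SD > 1 at 1-3 reads) then dwarfs the
#' biological signal, while the manifold still pools information across
#' events and cells.
#'
#' @inheritParams sim_params
#' @param ... further overrides passed to [sim_params()].
#' @return a `gedi_sim_params`.
#' @export
sim_params_paired <- function(G = 200, N = 2000, Q = 4, K_arch = 4, L = 2,
                              seed = 1, baseline_sd = 1.5,
                              archetype_sd = 0.22, tau = 0.1, omega = 0.05,
                              sigma_range = c(0.02, 0.05), ...) {
  sim_params(G = G, N = N, Q = Q, K_arch = K_arch, L = L, seed = seed,
             baseline_sd = baseline_sd, archetype_sd = archetype_sd,
             tau = tau, omega = omega, sigma_range = sigma_range, ...)
}

#' Simulate paired success/failure counts with a known logit field
#'
#' Fixture generator for the paired-binomial layer: the same archetype
#' machinery produces a smooth latent field, interpreted directly as the
#' logit of the success proportion (e.g. logit PSI); per-event totals are
#' Poisson at a configurable depth and successes binomial at the latent
#' proportion.
#'
#' @param params a `gedi_sim_params` (the latent field uses `baseline`,
#'   `X`, `H`, `W` etc. as in [simulate_cohort()]).
#' @param depth mean total count per (event, cell); 0 gives all-zero
#'   matrices with the truth retained.
#' @param seed seed of the noise draws (see [simulate_cohort()]).
#' @return object of class `gedi_sim_paired`: list with `M1`, `M2`,
#'   `truth_logit` (G x N latent logits), `sample_map`, `params`.
#' @export
simulate_paired <- function(params, depth = 2, seed = params$seed + 2L) {
  if (depth < 0) gedi_stop("depth must be >= 0")
  set.seed(seed)
  lat <- simulate_latent(params)
  y <- lat$Y
  tot <- matrix(stats::rpois(length(y), depth), nrow(y), ncol(y))
  M1 <- matrix(stats::rbinom(length(y), tot, sigmoid(y)), nrow(y), ncol(y))
  M2 <- tot - M1
  dn <- list(paste0("e", seq_len(params$G)),
             paste0("cell", seq_len(params$N)))
  dimnames(M1) <- dimnames(M2) <- dimnames(y) <- dn
  structure(list(M1 = M1, M2 = M2, truth_logit = y,
                 sample_map = paste0("sample", params$sample_map),
                 params = params),
            class = "gedi_sim_paired")
}
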