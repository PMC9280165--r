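# Seeded forward-model generators mirroring the two analysis models: the
# additive-plus-low-rank-interaction two-way table (AMMI) and the
# split-split-plot design with its three error strata. Both are exact
# inverses of the fitting code on noiseless input, which the tests exploit.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random orthonormal, column-centered score matrices
#'
#' Builds a k x rank matrix with orthonormal columns each summing to zero:
#' seeded Gaussian draws are column-centered (projecting out the constant
#' vector) and orthonormalized by QR. Suitable as genotype or tissue score
#' matrices of an AMMI simulation spec.
#'
#' @param k Number of rows (genes or tissues).
#' @param rank Number of columns; must be <= k - 1.
#' @param seed Integer seed.
#' @return k x rank matrix.
#' @export
random_interaction_scores <- function(k, rank, seed = 1L) {
  if (rank > k - 1) stop("rank must be at most k - 1")
  with_seed(seed, {
    z <- matrix(stats::rnorm(k * rank), k, rank)
    z <- sweep(z, 2, colMeans(z))      # column space orthogonal to 1
    qr.Q(qr(z))[, seq_len(rank), drop = FALSE]
  })
}

#' Simulation spec for the additive-plus-multiplicative-interaction model
#'
#' @param g,e,r Numbers of genes, tissues and replicates.
#' @param mu Grand mean.
#' @param alpha Genotype deviations, length g, sum 0 (default 0).
#' @param beta Tissue deviations, length e, sum 0 (default 0).
#' @param lambda Singular values of the interaction, descending (default
#'   none: purely additive table).
#' @param gamma,delta Score matrices (g x N and e x N, orthonormal
#'   zero-sum columns); defaults are seeded random ones via
#'   [random_interaction_scores()].
#' @param noise_sd Replicate-level Gaussian noise SD.
#' @param seed Integer seed for the replicate noise (and default scores).
#' @return List of class `ammi_sim_spec`.
#' @export
ammi_sim_spec <- function(g, e, r, mu = 0, alpha = rep(0, g), beta = rep(0, e),
                          lambda = numeric(0), gamma = NULL, delta = NULL,
                          noise_sd = 1, seed = 1L) {
  if (g < 2 || e < 2 || r < 1) stop("need g >= 2, e >= 2, r >= 1")
  rank <- length(lambda)
  if (rank > min(g - 1, e - 1))
    stop("interaction rank exceeds min(g - 1, e - 1)")
  if (is.unsorted(rev(lambda))) stop("lambda must be in descending order")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (length(alpha) != g || abs(sum(alpha)) > 1e-8 * (1 + max(abs(alpha))))
    stop("alpha must have length g and sum to zero")
  if (length(beta) != e || abs(sum(beta)) > 1e-8 * (1 + max(abs(beta))))
    stop("beta must have length e and sum to zero")
  if (rank > 0) {
    if (is.null(gamma)) gamma <- random_interaction_scores(g, rank, seed + 1L)
    if (is.null(delta)) delta <- random_interaction_scores(e, rank, seed + 2L)
    ortho <- function(m, k) {
      is.matrix(m) && nrow(m) == k && ncol(m) == rank &&
        max(abs(crossprod(m) - diag(rank))) < 1e-8 &&
        max(abs(colSums(m))) < 1e-8
    }
    if (!ortho(gamma, g))
      stop("gamma must be g x N with orthonormal zero-sum columns")
    if (!ortho(delta, e))
      stop("delta must be e x N with orthonormal zero-sum columns")
  } else gamma <- delta <- NULL
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(g = g, e = e, r = r, mu = mu, alpha = alpha, beta = beta,
                 lambda = lambda, gamma = gamma, delta = delta,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ammi_sim_spec")
}

#' Simulate replicate-level data from an AMMI forward model
#'
#' Cell expectation is `mu + alpha_g + beta_e + sum_n lambda_n gamma_gn
#' delta_en`; each of the `r` replicates adds independent Gaussian noise.
#' Deterministic given the spec's seed; the global RNG state is untouched.
#'
#' @param spec An [ammi_sim_spec()].
#' @param condition Label stored in the `condition` column (default 1).
#' @return Long-format expression table (genes `G1..`, tissues `E1..`).
#' @export
simulate_ammi <- function(spec, condition = 1) {
  stopifnot(inherits(spec, "ammi_sim_spec"))
  mu_ge <- matrix(spec$mu, spec$g, spec$e) + outer(spec$alpha, spec$beta, "+")
  if (length(spec$lambda))
    mu_ge <- mu_ge + spec$gamma %*% diag(spec$lambda, length(spec$lambda)) %*%
      t(spec$delta)
  cells <- expand.grid(gene = paste0("G", seq_len(spec$g)),
                       tissue = paste0("E", seq_len(spec$e)),
                       block = seq_len(spec$r), stringsAsFactors = FALSE)
  noise <- with_seed(spec$seed,
                     stats::rnorm(nrow(cells), sd = spec$noise_sd))
  data.frame(condition = condition, tissue = cells$tissue, gene = cells$gene,
             block = cells$block,
             expression = as.vector(mu_ge)[rep(seq_len(spec$g * spec$e),
                                               spec$r)] + noise)
}

#' Simulation spec for the split-split-plot design
#'
#' Fixed treatment effects default to zero; any subset can be supplied via
#' the `effects` list with elements `condition` (length t), `tissue`
#' (length s), `gene` (length g) and interaction arrays
#' `condition_tissue` (t x s), `condition_gene` (t x g), `tissue_gene`
#' (s x g), `condition_tissue_gene` (t x s x g). The three error strata have
#' SDs `sigma_f` (main plot), `sigma_g` (sub plot) and `sigma` (residual);
#' `block_sd` draws the block effects.
#'
#' @param b,t,s,g Numbers of blocks, conditions, tissues, genes (all >= 2).
#' @param mu Grand mean.
#' @param effects Named list of fixed-effect arrays (see above).
#' @param sigma_f,sigma_g,sigma Error-stratum SDs, all >= 0.
#' @param block_sd SD of random block effects (default 0).
#' @param seed Integer seed.
#' @return List of class `ssp_sim_spec`.
#' @export
ssp_sim_spec <- function(b, t, s, g, mu = 0, effects = list(),
                         sigma_f = 1, sigma_g = 1, sigma = 1,
                         block_sd = 0, seed = 1L) {
  if (any(c(b, t, s, g) < 2)) stop("b, t, s, g must all be >= 2")
  if (any(c(sigma_f, sigma_g, sigma, block_sd) < 0))
    stop("error-stratum SDs must be non-negative")
  allowed <- c("condition", "tissue", "gene", "condition_tissue",
               "condition_gene", "tissue_gene", "condition_tissue_gene")
  bad <- setdiff(names(effects), allowed)
  if (length(bad)) stop("unknown effect term(s): ", paste(bad, collapse = ", "))
  dims <- list(condition = t, tissue = s, gene = g,
               condition_tissue = c(t, s), condition_gene = c(t, g),
               tissue_gene = c(s, g), condition_tissue_gene = c(t, s, g))
  for (nm in names(effects)) {
    if (!isTRUE(all.equal(unname(dim(as.array(effects[[nm]]))), dims[[nm]])) &&
        !(is.null(dim(effects[[nm]])) && length(effects[[nm]]) == dims[[nm]][1] &&
          length(dims[[nm]]) == 1))
      stop("effect '", nm, "' has the wrong dimensions")
  }
  structure(list(b = b, t = t, s = s, g = g, mu = mu, effects = effects,
                 sigma_f = sigma_f, sigma_g = sigma_g, sigma = sigma,
                 block_sd = block_sd, seed = as.integer(seed)),
            class = "ssp_sim_spec")
}

#' Simulate a complete split-split-plot experiment
#'
#' Draws block effects, main-plot errors `f_ik`, sub-plot errors `g_ihk`
#' and residual errors `e_ihjk` at their respective strata and adds the
#' fixed treatment structure. Deterministic given the spec's seed.
#'
#' @param spec An [ssp_sim_spec()].
#' @return Long-format expression table with `b * t * s * g` records
#'   (conditions `C1..`, tissues `S1..`, genes `G1..`).
#' @export
simulate_ssp <- function(spec) {
  stopifnot(inherits(spec, "ssp_sim_spec"))
  b <- spec$b; t_ <- spec$t; s_ <- spec$s; g_ <- spec$g
  eff <- function(nm, dims) {
    x <- spec$effects[[nm]]
    if (is.null(x)) array(0, dims) else array(as.numeric(x), dims)
  }
  d <- array(0, c(t_, s_, g_))
  d <- d + array(eff("condition", t_), c(t_, s_, g_))
  d <- d + aperm(array(eff("tissue", s_), c(s_, t_, g_)), c(2, 1, 3))
  d <- d + aperm(array(eff("gene", g_), c(g_, t_, s_)), c(2, 3, 1))
  d <- d + array(eff("condition_tissue", c(t_, s_)), c(t_, s_, g_))
  d <- d + aperm(array(eff("condition_gene", c(t_, g_)), c(t_, g_, s_)), c(1, 3, 2))
  d <- d + aperm(array(eff("tissue_gene", c(s_, g_)), c(s_, g_, t_)), c(3, 1, 2))
  d <- d + eff("condition_tissue_gene", c(t_, s_, g_))

  grid <- expand.grid(gene = seq_len(g_), tissue = seq_len(s_),
                      condition = seq_len(t_), block = seq_len(b))
  y <- with_seed(spec$seed, {
    bk <- stats::rnorm(b, sd = spec$block_sd)
    f_ik <- matrix(stats::rnorm(t_ * b, sd = spec$sigma_f), t_, b)
    g_ihk <- array(stats::rnorm(t_ * s_ * b, sd = spec$sigma_g), c(t_, s_, b))
    e_res <- stats::rnorm(nrow(grid), sd = spec$sigma)
    spec$mu + bk[grid$block] +
      d[cbind(grid$condition, grid$tissue, grid$gene)] +
      f_ik[cbind(grid$condition, grid$block)] +
      g_ihk[cbind(grid$condition, grid$tissue, grid$block)] + e_res
  })
  data.frame(condition = paste0("C", grid$condition),
             tissue = paste0("S", grid$tissue),
             gene = paste0("G", grid$gene),
             block = grid$block, expression = y)
}
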