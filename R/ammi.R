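#' Build the gene-by-tissue matrix of cell means at one condition
#'
#' Sorts a summary table into the two-way genotype (gene) x environment
#' (tissue) table of cell means for a single condition, carrying along the
#' replicate count and the pooled within-cell error (from the per-cell SDs)
#' needed for AMMI F tests.
#'
#' @param summary Summary table covering the condition completely.
#' @param condition The condition (temperature) to extract.
#' @return An object of class `ge_matrix`: list with `means` (g x e matrix,
#'   genes in rows), `genes`, `tissues`, `condition`, `reps`, `error_ss`,
#'   `error_df`, `error_ms`.
#' @export
build_ge_matrix <- function(summary, condition) {
  validate_summary_table(summary)
  s <- summary[summary$condition == condition, , drop = FALSE]
  if (!nrow(s)) stop("no cells found for condition ", condition)
  genes <- unique(as.character(s$gene))
  tissues <- unique(as.character(s$tissue))
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(match(s$gene, genes), match(s$tissue, tissues))] <- s$mean
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing cell ", cell_label(condition, tissues[miss[2]], genes[miss[1]]))
  }
  if (length(unique(s$n)) != 1L)
    stop("replicate count must be constant across cells")
  err <- error_ss_from_sd(s)
  structure(list(means = m, genes = genes, tissues = tissues,
                 condition = condition, reps = s$n[1],
                 error_ss = err$ss, error_df = err$df,
                 error_ms = err$ss / err$df),
            class = "ge_matrix")
}

as_ge_means <- function(m) {
  if (inherits(m, "ge_matrix")) m$means else as.matrix(m)
}

#' Double-center a two-way table
#'
#' Removes the grand mean and both sets of marginal means, leaving the pure
#' interaction residual: `out[g, e] = y[g, e] - rowmean[g] - colmean[e] + grand`.
#' Rows and columns of the result each sum to zero.
#'
#' @param means A numeric matrix (or `ge_matrix`).
#' @return Matrix of the same shape.
#' @export
double_center <- function(means) {
  m <- as_ge_means(means)
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}

gollob_df <- function(g, e, n) g + e - 1 - 2 * n

#' AMMI decomposition of a gene-by-tissue table
#'
#' Fits the additive-main-effects-and-multiplicative-interaction model
#' \deqn{y_{ge} = \mu + \alpha_g + \beta_e + \sum_n \lambda_n \gamma_{gn} \delta_{en} + \theta_{ge}}
#' by double-centering the table of cell means and taking the SVD of the
#' interaction residual. The SS of the n-th interaction principal component
#' axis (IPCA) is `reps * lambda_n^2`; IPCA degrees of freedom follow
#' Gollob's rule `g + e - 1 - 2n`; all F tests use the pooled within-cell
#' error mean square as denominator. Percent-of-total SS uses
#' total = treatment + error.
#'
#' Axis signs are fixed by requiring the genotype score of the gene with the
#' largest main-effect deviation to be non-negative on every retained axis.
#'
#' @param m A `ge_matrix` from [build_ge_matrix()].
#' @param n_axes Number of IPCA axes reported individually (default 2); the
#'   remaining axes are pooled into the residual row.
#' @return Object of class `ammi`: grand mean, `alpha`, `beta`, singular
#'   values `lambda`, score matrices `gamma` (genes) and `delta` (tissues),
#'   `residual` (axes beyond `n_axes`), the `anova` table with percentage
#'   columns, `pct_of_total` and `pct_of_interaction`.
#' @export
ammi_fit <- function(m, n_axes = 2) {
  if (!inherits(m, "ge_matrix"))
    stop("'m' must be a ge_matrix (see build_ge_matrix)")
  y <- m$means
  g <- nrow(y); e <- ncol(y); r <- m$reps
  if (g < 2 || e < 2) stop("need at least 2 genes and 2 tissues")
  n_max <- min(g - 1, e - 1)
  n_axes <- min(n_axes, n_max)
  grand <- mean(y)
  alpha <- rowMeans(y) - grand
  beta <- colMeans(y) - grand
  dc <- double_center(y)
  sv <- svd(dc)
  lambda <- sv$d[seq_len(n_max)]
  gamma <- sv$u[, seq_len(n_max), drop = FALSE]
  delta <- sv$v[, seq_len(n_max), drop = FALSE]
  top <- which.max(alpha)
  for (k in seq_len(n_max)) {
    if (gamma[top, k] < 0) {
      gamma[, k] <- -gamma[, k]
      delta[, k] <- -delta[, k]
    }
  }
  dimnames(gamma) <- list(m$genes, paste0("IPCA", seq_len(n_max)))
  dimnames(delta) <- list(m$tissues, paste0("IPCA", seq_len(n_max)))

  ss_gene <- r * e * sum(alpha^2)
  ss_tissue <- r * g * sum(beta^2)
  ss_ipca <- r * lambda^2
  ss_int <- sum(ss_ipca)
  ss_trt <- ss_gene + ss_tissue + ss_int
  ss_total <- ss_trt + m$error_ss
  ss_resid <- sum(ss_ipca[-seq_len(n_axes)])

  df_ipca <- gollob_df(g, e, seq_len(n_max))
  df_int <- (g - 1) * (e - 1)
  df_resid <- df_int - sum(df_ipca[seq_len(n_axes)])
  src <- c("Total", "Treatment", "Gene", "Tissue", "Interaction",
           paste0("IPCA", seq_len(n_axes)), "Residual", "Error")
  df <- c(g * e * r - 1, g * e - 1, g - 1, e - 1, df_int,
          df_ipca[seq_len(n_axes)], df_resid, m$error_df)
  ss <- c(ss_total, ss_trt, ss_gene, ss_tissue, ss_int,
          ss_ipca[seq_len(n_axes)], ss_resid, m$error_ss)
  ms <- ss / df
  testable <- seq(2, 5 + n_axes)  # Treatment .. last reported IPCA
  f <- p <- rep(NA_real_, length(src))
  if (length(testable)) {
    if (m$error_ms <= 0) stop("error mean square must be positive for F tests")
    for (i in testable) {
      ft <- f_test(ms[i], df[i], m$error_ms, m$error_df)
      f[i] <- ft$f; p[i] <- ft$p
    }
  }
  anova <- new_anova_table(src, df, ss, ms, f, p)
  pct_total <- c(Gene = 100 * ss_gene / ss_total,
                 Tissue = 100 * ss_tissue / ss_total,
                 Interaction = 100 * ss_int / ss_total)
  pct_int <- 100 * ss_ipca / ss_int
  names(pct_int) <- paste0("IPCA", seq_len(n_max))
  anova$pct_total_ss <- NA_real_
  anova$pct_total_ss[match(names(pct_total), anova$source)] <- pct_total
  anova$pct_total_ss[match(paste0("IPCA", seq_len(n_axes)), anova$source)] <-
    pct_int[seq_len(n_axes)]

  structure(list(grand_mean = grand, alpha = alpha, beta = beta,
                 lambda = lambda, gamma = gamma, delta = delta,
                 reps = r, n_axes = n_axes,
                 residual = dc - gamma[, seq_len(n_axes), drop = FALSE] %*%
                   diag(lambda[seq_len(n_axes)], n_axes) %*%
                   t(delta[, seq_len(n_axes), drop = FALSE]),
                 anova = anova,
                 pct_of_total = pct_total, pct_of_interaction = pct_int,
                 condition = m$condition),
            class = "ammi")
}

#' @export
print.ammi <- function(x, ...) {
  cat("AMMI decomposition",
      if (!is.null(x$condition)) paste0(" (condition ", x$condition, ")"),
      "\n", sep = "")
  cat(sprintf("grand mean %.4g; %d gene(s) x %d tissue(s), %d replicate(s)\n",
              x$grand_mean, length(x$alpha), length(x$beta), x$reps))
  print(x$anova)
  cat("\n% of interaction SS by axis:\n")
  print(round(x$pct_of_interaction, 4))
  invisible(x)
}

#' IPCA score tables of an AMMI fit
#'
#' @param fit An `ammi` object.
#' @return Data.frame with entity, type (gene/tissue) and the IPCA scores.
#' @export
ammi_scores <- function(fit) {
  k <- fit$n_axes
  rbind(
    data.frame(entity = rownames(fit$gamma), type = "gene",
               fit$gamma[, seq_len(k), drop = FALSE], row.names = NULL),
    data.frame(entity = rownames(fit$delta), type = "tissue",
               fit$delta[, seq_len(k), drop = FALSE], row.names = NULL))
}
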