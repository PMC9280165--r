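# Small in-code fixtures shared across test files.

# random balanced summary table (complete crossing, constant n)
random_summary <- function(nc = 2, nt = 3, ng = 4, n = 3, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(condition = seq_len(nc) * 5,
                       tissue = paste0("T", seq_len(nt)),
                       gene = paste0("G", seq_len(ng)),
                       stringsAsFactors = FALSE)
  data.frame(cells,
             mean = stats::runif(nrow(cells), 1, 100),
             sd = stats::runif(nrow(cells), 0.1, 5),
             n = n)
}

# additive two-way surface plus an explicit rank-1 interaction
rank1_ge_matrix <- function(g = 4, e = 6, r = 3, lambda = 10, seed = 2) {
  u <- random_interaction_scores(g, 1, seed)
  v <- random_interaction_scores(e, 1, seed + 1)
  alpha <- scale(seq_len(g), scale = FALSE)[, 1]
  beta <- scale(seq_len(e)^2, scale = FALSE)[, 1]
  means <- 50 + outer(alpha, beta, "+") + lambda * tcrossprod(u, v)
  dimnames(means) <- list(paste0("G", seq_len(g)), paste0("E", seq_len(e)))
  structure(list(means = means, genes = rownames(means),
                 tissues = colnames(means), condition = 1, reps = r,
                 error_ss = 2, error_df = (r - 1) * g * e,
                 error_ms = 2 / ((r - 1) * g * e)),
            class = "ge_matrix")
}

tk_fixture <- function() load_takifugu_cold()

tk_ammi <- function(condition, ...) {
  ammi_fit(build_ge_matrix(tk_fixture(), condition), ...)
}

tk_gge <- function(condition, config = gge_config()) {
  gge_decompose(build_ge_matrix(tk_fixture(), condition), config)
}

# geometric which-won-where oracle: assign each tissue to the sector of the
# convex-hull vertex maximizing the projection along the tissue direction,
# by explicit angle comparison against the perpendicular boundary rays
geometric_winners <- function(model) {
  G <- model$gene_coords
  E <- model$tissue_coords
  hull <- grDevices::chull(G[, 1], G[, 2])
  out <- character(nrow(E))
  for (e in seq_len(nrow(E))) {
    proj <- drop(G[hull, , drop = FALSE] %*% E[e, ])
    out[e] <- rownames(G)[hull[which.max(proj)]]
  }
  names(out) <- rownames(E)
  out
}
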