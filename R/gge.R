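#' GGE biplot configuration
#'
#' The GGE model removes the environment (tissue) main effect by column
#' centering and submits the remainder — genotype main effect plus
#' genotype x environment interaction — to SVD. `scaling = "sd"` divides
#' each centered tissue column by its standard deviation. `svp` controls
#' how the singular values are partitioned between the two coordinate sets:
#' gene scores are `gamma * lambda^f` and tissue scores `delta * lambda^(1-f)`
#' with f = 1 (`"genotype"`), 0 (`"environment"`) or 1/2 (`"symmetric"`).
#'
#' @param scaling `"none"` (default) or `"sd"`.
#' @param svp `"symmetric"` (default), `"genotype"` or `"environment"`.
#' @return List of class `gge_config`.
#' @export
gge_config <- function(scaling = c("none", "sd"),
                       svp = c("symmetric", "genotype", "environment")) {
  structure(list(centering = "tissue",
                 scaling = match.arg(scaling),
                 svp = match.arg(svp)),
            class = "gge_config")
}

svp_exponent <- function(svp) {
  switch(svp, genotype = 1, environment = 0, symmetric = 0.5)
}

#' Two-principal-component GGE decomposition
#'
#' Fits \deqn{y_{ge} = \mu + \beta_e + \lambda_1\gamma_{g1}\delta_{e1} +
#' \lambda_2\gamma_{g2}\delta_{e2} + \theta_{ge}} by SVD of the
#' tissue-centered (optionally scaled) matrix. The product of the gene and
#' tissue coordinate matrices reconstructs the centered matrix regardless of
#' the singular-value partition, truncated at two axes for the biplot views.
#'
#' Sign convention: PC1 is flipped so the average tissue vector points in
#' the positive direction; PC2 so the tissue with the largest absolute
#' loading is positive.
#'
#' @param m A `ge_matrix` or a plain genes x tissues matrix.
#' @param config A [gge_config()].
#' @return Object of class `gge`: `gene_coords` and `tissue_coords`
#'   (2 columns), full `u`, `d`, `v` of the SVD, `centered` matrix,
#'   `pct_variance` (percent of G+GE SS per PC), `config`.
#' @export
gge_decompose <- function(m, config = gge_config()) {
  y <- as_ge_means(m)
  if (nrow(y) < 3) stop("need at least 3 genes for 2-PC biplot views")
  centered <- sweep(y, 2, colMeans(y))
  if (config$scaling == "sd") {
    s <- apply(y, 2, stats::sd)
    if (any(s == 0)) stop("cannot scale: zero-variance tissue column(s)")
    centered <- sweep(centered, 2, s, "/")
  }
  if (all(abs(centered) < .Machine$double.eps * 100))
    stop("degenerate input: centered matrix is zero (no G or GE variation)")
  sv <- svd(centered)
  rank <- min(dim(y))
  if (sv$d[2] <= sv$d[1] * 1e-12 && rank >= 2)
    warning("second singular value is numerically zero; 2-PC views are degenerate")
  u <- sv$u; v <- sv$v; d <- sv$d
  # deterministic axis orientation
  if (sum(v[, 1]) < 0) { u[, 1] <- -u[, 1]; v[, 1] <- -v[, 1] }
  if (rank >= 2 && v[which.max(abs(v[, 2])), 2] < 0) {
    u[, 2] <- -u[, 2]; v[, 2] <- -v[, 2]
  }
  f <- svp_exponent(config$svp)
  gene_coords <- u[, 1:2, drop = FALSE] %*% diag(d[1:2]^f, 2)
  tissue_coords <- v[, 1:2, drop = FALSE] %*% diag(d[1:2]^(1 - f), 2)
  dimnames(gene_coords) <- list(rownames(y), c("PC1", "PC2"))
  dimnames(tissue_coords) <- list(colnames(y), c("PC1", "PC2"))
  structure(list(gene_coords = gene_coords, tissue_coords = tissue_coords,
                 u = u, d = d, v = v, rank = rank, centered = centered,
                 pct_variance = 100 * d[1:2]^2 / sum(d^2),
                 config = config,
                 condition = if (inherits(m, "ge_matrix")) m$condition),
            class = "gge")
}

#' @export
print.gge <- function(x, ...) {
  cat("GGE biplot model",
      if (!is.null(x$condition)) paste0(" (condition ", x$condition, ")"),
      "\n", sep = "")
  cat(sprintf("centering: %s, scaling: %s, SVP: %s\n", x$config$centering,
              x$config$scaling, x$config$svp))
  cat(sprintf("PC1 %.2f%%, PC2 %.2f%% of G+GE SS\n",
              x$pct_variance[1], x$pct_variance[2]))
  invisible(x)
}

# rank-2 reconstruction of the centered matrix; identical under every SVP
gge_rank2 <- function(model) {
  model$gene_coords %*% t(model$tissue_coords)
}

#' Relationships among tissues: angles, cosines, discriminating ability
#'
#' In the biplot the cosine of the angle between two tissue vectors
#' approximates the correlation of gene expression between the two tissues,
#' and the vector length measures the tissue's ability to discriminate the
#' genes. With `n_axes = model$rank` (full rank) the cosine equals the
#' gene-wise Pearson correlation of the two centered tissue columns exactly
#' when tissue coordinates carry the full singular values
#' (environment-focused SVP).
#'
#' @param model A `gge` model.
#' @param n_axes Number of axes used (default 2, the biplot view).
#' @return List with `cosine` (e x e matrix), `angle` (degrees),
#'   `length` (vector lengths), `discrimination` (tissues ranked by length),
#'   `degenerate` (names of zero-length tissue vectors, if any).
#' @export
tissue_relationships <- function(model, n_axes = 2) {
  stopifnot(inherits(model, "gge"))
  n_axes <- min(n_axes, model$rank)
  f <- svp_exponent(model$config$svp)
  tc <- model$v[, seq_len(n_axes), drop = FALSE] %*%
    diag(model$d[seq_len(n_axes)]^(1 - f), n_axes)
  rownames(tc) <- rownames(model$tissue_coords)
  len <- sqrt(rowSums(tc^2))
  degenerate <- names(len)[len == 0]
  ip <- tc %*% t(tc)
  denom <- outer(len, len)
  cosine <- ifelse(denom > 0, ip / denom, NA_real_)
  cosine <- pmin(pmax(cosine, -1), 1)
  diag(cosine)[len > 0] <- 1
  list(cosine = cosine,
       angle = acos(cosine) * 180 / pi,
       length = len,
       discrimination = names(sort(len, decreasing = TRUE)),
       degenerate = degenerate)
}

#' Which-won-where sector partition
#'
#' Draws the convex hull around the gene points of the biplot; rays from the
#' origin perpendicular to the hull edges divide the plane into sectors, and
#' the hull vertex inside a sector is the highest-expressed ("winning") gene
#' for every tissue falling in that sector. Winners are computed as the
#' argmax over genes of the rank-2 reconstructed centered expression — the
#' geometric sector winner — which makes the assignment invariant to the
#' singular-value partition. Ties go to the gene with the larger PC1 score.
#'
#' @param model A `gge` model.
#' @return Object of class `gge_sectors`: `hull` (gene names,
#'   counterclockwise), `rays` (boundary angles in radians), `winners`
#'   (named character vector, one winner per tissue) and `regions` (tissues
#'   grouped by winner).
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge"))
  G <- model$gene_coords
  if (nrow(G) < 3) stop("need at least 3 gene points")
  hull_idx <- grDevices::chull(G[, 1], G[, 2])  # clockwise per ?chull
  if (length(hull_idx) < 3)
    stop("degenerate geometry: gene points are collinear")
  hull_idx <- rev(hull_idx)  # counterclockwise
  R2 <- gge_rank2(model)
  winners <- character(ncol(R2))
  for (e in seq_len(ncol(R2))) {
    best <- which(R2[, e] == max(R2[, e]))
    if (length(best) > 1) best <- best[which.max(G[best, 1])]
    winners[e] <- rownames(G)[best]
  }
  names(winners) <- colnames(R2)
  # boundary rays: perpendicular to each hull edge, through the origin
  hp <- G[hull_idx, , drop = FALSE]
  nh <- nrow(hp)
  edges <- cbind(seq_len(nh), c(seq_len(nh)[-1], 1L))
  rays <- atan2(hp[edges[, 1], 1] - hp[edges[, 2], 1],
                hp[edges[, 2], 2] - hp[edges[, 1], 2])
  structure(list(hull = rownames(G)[hull_idx], rays = sort(rays),
                 winners = winners,
                 regions = split(names(winners), winners)),
            class = "gge_sectors")
}

#' @export
print.gge_sectors <- function(x, ...) {
  cat("which-won-where partition\n")
  cat("hull (counterclockwise):", paste(x$hull, collapse = ", "), "\n")
  for (w in names(x$regions))
    cat(sprintf("  %s wins in: %s\n", w, paste(x$regions[[w]], collapse = ", ")))
  invisible(x)
}

average_tissue_axis <- function(model) {
  ata <- colMeans(model$tissue_coords)
  norm <- sqrt(sum(ata^2))
  if (norm < .Machine$double.eps * 100)
    stop("average tissue vector is zero: no meaningful average-tissue axis")
  ata / norm
}

#' Mean performance and stability of the genes
#'
#' Projects each gene point onto the average-tissue axis (ATA, the direction
#' of the mean tissue vector): the signed projection estimates the gene's
#' average expression over tissues, and the absolute perpendicular deviation
#' from the axis estimates its instability (the larger, the less stable).
#'
#' @param model A `gge` model (genotype or symmetric SVP recommended, so the
#'   gene points carry the genotype pattern).
#' @return Object of class `gge_ranking` with `mean_scores`,
#'   `stability_scores` (absolute perpendicular deviation, >= 0),
#'   `mean_order` (decreasing mean) and `stability_order`
#'   (most stable first).
#' @export
mean_stability <- function(model) {
  stopifnot(inherits(model, "gge"))
  ata <- average_tissue_axis(model)
  G <- model$gene_coords
  mean_scores <- drop(G %*% ata)
  perp <- G - outer(mean_scores, ata)
  stability_scores <- sqrt(rowSums(perp^2))
  structure(list(mean_scores = mean_scores,
                 stability_scores = stability_scores,
                 mean_order = names(sort(mean_scores, decreasing = TRUE)),
                 stability_order = names(sort(stability_scores))),
            class = "gge_ranking")
}

#' Distance to the ideal gene
#'
#' The ideal gene sits on the average-tissue axis at the largest observed
#' mean score with zero instability; the Euclidean distance of each gene
#' point to it combines expression level and stability into one
#' comprehensive ranking (smallest distance first).
#'
#' @param model A `gge` model.
#' @return Object of class `gge_ranking` with `ideal_point`,
#'   `ideal_distances` and `comprehensive_order`, plus the mean/stability
#'   components from [mean_stability()].
#' @export
ideal_gene_distance <- function(model) {
  ms <- mean_stability(model)
  ata <- average_tissue_axis(model)
  ideal <- ata * max(ms$mean_scores)
  G <- model$gene_coords
  d <- sqrt(rowSums(sweep(G, 2, ideal)^2))
  structure(c(ms, list(ideal_point = ideal, ideal_distances = d,
                       comprehensive_order = names(sort(d)))),
            class = "gge_ranking")
}

#' @export
print.gge_ranking <- function(x, ...) {
  cat("GGE gene ranking\n")
  cat("  mean order      :", paste(x$mean_order, collapse = " > "), "\n")
  cat("  stability order :", paste(x$stability_order, collapse = " > "),
      "(most stable first)\n")
  if (!is.null(x$comprehensive_order))
    cat("  comprehensive   :", paste(x$comprehensive_order, collapse = " > "),
        "(closest to ideal first)\n")
  invisible(x)
}

#' Biplot coordinate table
#'
#' @param model A `gge` model.
#' @return Data.frame `entity, type, PC1, PC2` for CSV export.
#' @export
gge_coordinates <- function(model) {
  rbind(
    data.frame(entity = rownames(model$gene_coords), type = "gene",
               PC1 = model$gene_coords[, 1], PC2 = model$gene_coords[, 2],
               row.names = NULL),
    data.frame(entity = rownames(model$tissue_coords), type = "tissue",
               PC1 = model$tissue_coords[, 1], PC2 = model$tissue_coords[, 2],
               row.names = NULL))
}

#' Plot a GGE biplot view
#'
#' Thin base-graphics rendering of the four standard views; the coordinate
#' tables are the primary output, the figure is a convenience.
#'
#' @param x A `gge` model.
#' @param type One of `"relationships"`, `"which-won-where"`,
#'   `"mean-stability"`, `"ideal"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gge <- function(x, type = c("relationships", "which-won-where",
                                 "mean-stability", "ideal"), ...) {
  type <- match.arg(type)
  G <- x$gene_coords; E <- x$tissue_coords
  lim <- range(c(G, E, 0)) * 1.1
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = sprintf("PC1 (%.1f%%)", x$pct_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$pct_variance[2]),
                 main = paste("GGE:", type), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (type == "relationships")
    graphics::segments(0, 0, E[, 1], E[, 2], col = "steelblue")
  if (type == "which-won-where") {
    s <- which_won_where(x)
    hp <- G[s$hull, , drop = FALSE]
    graphics::polygon(hp[, 1], hp[, 2], border = "grey40")
    big <- max(abs(lim)) * 2
    graphics::segments(0, 0, big * cos(s$rays), big * sin(s$rays),
                       lty = 2, col = "grey60")
  }
  if (type %in% c("mean-stability", "ideal")) {
    ata <- average_tissue_axis(x)
    big <- max(abs(lim)) * 2
    graphics::segments(-big * ata[1], -big * ata[2], big * ata[1],
                       big * ata[2], col = "grey40")
    if (type == "ideal") {
      r <- ideal_gene_distance(x)
      graphics::points(r$ideal_point[1], r$ideal_point[2], pch = 8, col = "red")
      graphics::symbols(rep(r$ideal_point[1], 3), rep(r$ideal_point[2], 3),
                        circles = max(r$ideal_distances) * c(1, 2, 3) / 3,
                        add = TRUE, inches = FALSE, fg = "grey75")
    }
  }
  graphics::points(E, pch = 4, col = "steelblue")
  graphics::text(E, labels = rownames(E), pos = 3, cex = 0.8, col = "steelblue")
  graphics::points(G, pch = 19, col = "firebrick")
  graphics::text(G, labels = rownames(G), pos = 3, cex = 0.9, col = "firebrick")
  invisible(x)
}
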