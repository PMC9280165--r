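test_that("a rank-1 centered matrix puts 100% of G+GE variance on PC1", {
  m <- rank1_ge_matrix(lambda = 0)  # additive only: G pattern is rank 1
  means <- m$means
  centered <- sweep(means, 2, colMeans(means))
  expect_equal(qr(centered)$rank, 1L)
  model <- suppressWarnings(gge_decompose(m))
  expect_equal(model$pct_variance[1], 100, tolerance = 1e-9)
})

test_that("gene x tissue coordinate products reconstruct the centered matrix", {
  tk <- tk_fixture()
  for (svp in c("genotype", "environment", "symmetric")) {
    model <- tk_gge(5, gge_config(svp = svp))
    # full-rank product over all axes
    f <- if (svp == "genotype") 1 else if (svp == "environment") 0 else 0.5
    G <- model$u %*% diag(model$d^f)
    E <- model$v %*% diag(model$d^(1 - f))
    expect_equal(unname(G %*% t(E)), unname(model$centered), tolerance = 1e-8)
    # 2-PC truncation error is the sum of discarded squared singular values
    R2 <- model$gene_coords %*% t(model$tissue_coords)
    expect_equal(sum((model$centered - R2)^2), sum(model$d[-(1:2)]^2),
                 tolerance = 1e-8)
  }
  # genotype SVP gene scores are the left singular vectors scaled by lambda
  mg <- tk_gge(5, gge_config(svp = "genotype"))
  expect_equal(abs(unname(mg$gene_coords)),
               abs(unname(mg$u[, 1:2] %*% diag(mg$d[1:2]))), tolerance = 1e-9)
})

test_that("the first two PCs dominate the fixture's G+GE structure", {
  for (cond in c(5, 8, 13, 18))
    expect_gte(sum(tk_gge(cond)$pct_variance), 95)
})

test_that("full-rank tissue-vector cosines equal expression correlations", {
  model <- tk_gge(5, gge_config(svp = "environment"))
  rel <- tissue_relationships(model, n_axes = model$rank)
  corr <- stats::cor(model$centered)
  expect_equal(unname(rel$cosine), unname(corr), tolerance = 1e-8)
})

test_that("duplicated tissue columns have cosine 1 and angle 0", {
  m <- rank1_ge_matrix(g = 4, e = 5, lambda = 8)
  m$means <- cbind(m$means, dup = m$means[, 1])
  m$tissues <- colnames(m$means)
  model <- gge_decompose(m)
  rel <- tissue_relationships(model)
  expect_equal(rel$cosine["E1", "dup"], 1, tolerance = 1e-9)
  expect_equal(rel$angle["E1", "dup"], 0, tolerance = 1e-4)
})

test_that("discriminating tissues match the published top ranks", {
  rel5 <- tissue_relationships(tk_gge(5))
  expect_equal(rel5$discrimination[1:2], c("Muscle", "Skin"))
  rel8 <- tissue_relationships(tk_gge(8))
  expect_equal(rel8$discrimination[1:2], c("Spleen", "Kidney"))
})

test_that("sector winners agree with the geometric hull-sector oracle", {
  tk <- tk_fixture()
  for (cond in c(5, 8, 13, 18)) {
    model <- tk_gge(cond)
    expect_identical(which_won_where(model)$winners, geometric_winners(model))
  }
  set.seed(14)
  for (i in 1:10) {
    means <- matrix(rnorm(4 * 7, 20, 5), 4, 7,
                    dimnames = list(paste0("G", 1:4), paste0("E", 1:7)))
    model <- gge_decompose(means)
    expect_identical(which_won_where(model)$winners, geometric_winners(model))
  }
})

test_that("winners match the argmax of rank-2 reconstructed expression", {
  for (cond in c(5, 8, 13, 18)) {
    model <- tk_gge(cond)
    R2 <- model$gene_coords %*% t(model$tissue_coords)
    best <- rownames(model$gene_coords)[apply(R2, 2, which.max)]
    expect_identical(unname(which_won_where(model)$winners), best)
  }
})

test_that("winners and mean order are invariant to the SVP choice", {
  for (cond in c(5, 13, 18)) {
    ref <- NULL
    for (svp in c("genotype", "environment", "symmetric")) {
      model <- tk_gge(cond, gge_config(svp = svp))
      got <- list(which_won_where(model)$winners,
                  mean_stability(model)$mean_order)
      if (is.null(ref)) ref <- got else expect_identical(got, ref)
    }
  }
})

test_that("one dominant gene wins every tissue in a single sector", {
  set.seed(6)
  means <- matrix(rnorm(4 * 6, 10, 0.5), 4, 6,
                  dimnames = list(paste0("G", 1:4), paste0("E", 1:6)))
  means[2, ] <- means[2, ] + 50
  model <- gge_decompose(means)
  ww <- which_won_where(model)
  expect_true(all(ww$winners == "G2"))
  expect_length(ww$regions, 1L)
})

test_that("zero interaction gives zero instability and the additive order", {
  m <- rank1_ge_matrix(lambda = 0)
  model <- suppressWarnings(gge_decompose(m))
  rk <- mean_stability(model)
  expect_equal(unname(rk$stability_scores), rep(0, 4), tolerance = 1e-7)
  expect_identical(rk$mean_order,
                   names(sort(rowMeans(m$means), decreasing = TRUE)))
})

test_that("a gene at the ideal point has distance 0 and rank 1", {
  model <- tk_gge(5)
  rk <- ideal_gene_distance(model)
  shifted <- model
  shifted$gene_coords["CIRP", ] <- rk$ideal_point
  rk2 <- ideal_gene_distance(shifted)
  expect_equal(unname(rk2$ideal_distances["CIRP"]), 0, tolerance = 1e-9)
  expect_identical(rk2$comprehensive_order[1], "CIRP")
})

test_that("degenerate inputs are rejected", {
  expect_error(gge_decompose(matrix(5, 4, 6)), "degenerate")
  m <- matrix(rnorm(12), 2, 6)
  expect_error(gge_decompose(m), "at least 3 genes")
})
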