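test_that("factorial SS vanishes on a constant table and matches aov", {
  s <- random_summary(nc = 2, nt = 3, ng = 4, seed = 8)
  const <- s; const$mean <- 7; const$sd <- 0
  terms <- list("condition", "tissue", "gene", c("condition", "tissue"),
                c("condition", "gene"), c("tissue", "gene"),
                c("condition", "tissue", "gene"))
  for (term in terms) expect_equal(factorial_ss(const, term), 0)

  # independent oracle: replicate-level aov on expanded data
  long <- expand_summary(s, seed = 8)
  long$condition <- factor(long$condition)
  fit <- summary(stats::aov(expression ~ condition * tissue * gene, data = long))
  ss_aov <- fit[[1]][["Sum Sq"]]
  labels <- trimws(rownames(fit[[1]]))
  for (term in terms) {
    lab <- paste(term, collapse = ":")
    expect_equal(factorial_ss(s, term), ss_aov[match(lab, labels)],
                 tolerance = 1e-8, label = lab)
  }
})

test_that("main-effect and interaction SS add up to the treatment SS", {
  for (seed in c(2, 17, 31)) {
    s <- random_summary(nc = 3, nt = 4, ng = 2, n = 2, seed = seed)
    terms <- list("condition", "tissue", "gene", c("condition", "tissue"),
                  c("condition", "gene"), c("tissue", "gene"),
                  c("condition", "tissue", "gene"))
    total_trt <- sum(vapply(terms, function(tm) factorial_ss(s, tm), 0))
    long <- expand_summary(s, seed = seed)
    cellmeans <- summarize_expression(long)
    grand <- mean(rep(cellmeans$mean, cellmeans$n))
    direct <- sum(cellmeans$n * (cellmeans$mean - grand)^2)
    expect_equal(total_trt, direct, tolerance = 1e-8)
  }
})

test_that("unbalanced replication is rejected", {
  s <- random_summary(seed = 5)
  s$n[1] <- 4
  expect_error(factorial_ss(s, "gene"), "unbalanced")
})

test_that("pooled error SS equals sum of (n-1) sd^2", {
  s <- random_summary(seed = 6)
  err <- error_ss_from_sd(s)
  expect_equal(err$ss, sum((s$n - 1) * s$sd^2))
  expect_equal(err$df, sum(s$n - 1))
  s$sd <- 0
  expect_equal(error_ss_from_sd(s)$ss, 0)
})

test_that("F ratios and upper-tail p values match the published rows", {
  ft <- f_test(83864818, 3, 93418.28, 72)
  expect_equal(ft$f, 897.73, tolerance = 5e-5)
  expect_lt(ft$p, 1e-10)
  expect_equal(f_test(619861, 3, 770.098, 72)$f, 804.91, tolerance = 5e-5)
  expect_equal(f_test(5, 3, 5, 10)$f, 1)
  expect_equal(f_test(5, 3, 5, 10)$p, stats::pf(1, 3, 10, lower.tail = FALSE))
  expect_error(f_test(1, 3, 0, 10), "positive")
})

test_that("split-split-plot strata match the aov error decomposition", {
  spec <- ssp_sim_spec(b = 3, t = 3, s = 4, g = 2, mu = 10,
                       effects = list(condition = c(-1, 0, 1),
                                      tissue_gene = matrix(1:8 - 4.5, 4, 2)),
                       sigma_f = 2, sigma_g = 1.5, sigma = 1,
                       block_sd = 1, seed = 42)
  table <- simulate_ssp(spec)
  tab <- split_split_plot_anova(table)

  d <- table
  d[c("condition", "tissue", "gene", "block")] <-
    lapply(d[c("condition", "tissue", "gene", "block")], factor)
  oracle <- suppressWarnings(  # aov flags the explicit strata as singular
    stats::aov(expression ~ block + condition * tissue * gene +
                 Error(block:condition + block:condition:tissue), data = d))
  os <- summary(oracle)
  get_ss <- function(stratum, label) {
    df <- os[[stratum]][[1]]
    df[["Sum Sq"]][match(label, trimws(rownames(df)))]
  }
  expect_equal(tab$ss[tab$source == "Condition"],
               get_ss("Error: block:condition", "condition"), tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Main-plot error"],
               get_ss("Error: block:condition", "Residuals"), tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Tissue"],
               get_ss("Error: block:condition:tissue", "tissue"), tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Condition:Tissue"],
               get_ss("Error: block:condition:tissue", "condition:tissue"),
               tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Sub-plot error"],
               get_ss("Error: block:condition:tissue", "Residuals"),
               tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Gene"],
               get_ss("Error: Within", "gene"), tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Sub-sub-plot error"],
               get_ss("Error: Within", "Residuals"), tolerance = 1e-8)
})

test_that("SS decomposition is exhaustive and df sum to N - 1", {
  for (seed in c(1, 9)) {
    spec <- ssp_sim_spec(b = 3, t = 4, s = 3, g = 3, sigma_f = 1,
                         sigma_g = 1, sigma = 1, block_sd = 0.5, seed = seed)
    table <- simulate_ssp(spec)
    tab <- split_split_plot_anova(table)
    expect_true(all(tab$ss >= 0))
    expect_equal(sum(tab$df), nrow(table) - 1)
    expect_equal(sum(tab$ss), sum((table$expression - mean(table$expression))^2),
                 tolerance = 1e-8)
  }
})

test_that("a zero-noise design recovers the injected effect SS exactly", {
  t_eff <- c(-3, 1, 2)
  spec <- ssp_sim_spec(b = 2, t = 3, s = 3, g = 2, mu = 5,
                       effects = list(condition = t_eff),
                       sigma_f = 0, sigma_g = 0, sigma = 0, seed = 1)
  tab <- split_split_plot_anova(simulate_ssp(spec))
  b <- 2; s_ <- 3; g_ <- 2
  expect_equal(tab$ss[tab$source == "Condition"],
               b * s_ * g_ * sum(t_eff^2), tolerance = 1e-10)
  other <- setdiff(tab$source, "Condition")
  expect_equal(tab$ss[tab$source %in% other], rep(0, length(other)),
               tolerance = 1e-8)
})

test_that("missing design cells are reported", {
  table <- simulate_ssp(ssp_sim_spec(b = 2, t = 2, s = 2, g = 2, seed = 3))
  expect_error(split_split_plot_anova(table[-1, ]), "missing 1 cell")
})
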