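#' @importFrom stats pf
NULL

new_anova_table <- function(source, df, ss, ms, f, p) {
  out <- data.frame(source = source, df = as.integer(df), ss = ss, ms = ms,
                    f = f, p = p, stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  stars <- ifelse(is.na(y$p), "",
                  ifelse(y$p < 0.01, "**", ifelse(y$p < 0.05, "*", "")))
  y$f <- ifelse(is.na(y$f), "", paste0(formatC(y$f, digits = 4, format = "g"), stars))
  y$p <- ifelse(is.na(x$p), "", formatC(x$p, digits = 4, format = "g"))
  y$ms <- ifelse(is.na(y$ms), "", formatC(y$ms, digits = 7, format = "g"))
  y$ss <- formatC(y$ss, digits = 8, format = "g")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write an ANOVA table as CSV
#'
#' Columns follow the conventional report order: source, df, SS, MS, F, p
#' (plus any percentage columns already attached to the table).
#'
#' @param table An `anova_table`.
#' @param path Output file path.
#' @export
write_anova_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cell-mean array over the three classification factors, levels in order of
# appearance; errors if the crossing is incomplete or replication unbalanced.
summary_cell_array <- function(summary) {
  validate_summary_table(summary)
  lev <- lapply(summary[c("condition", "tissue", "gene")],
                function(x) unique(as.character(x)))
  idx <- mapply(function(x, l) match(as.character(x), l),
                summary[c("condition", "tissue", "gene")], lev, SIMPLIFY = FALSE)
  dims <- lengths(lev)
  arr <- array(NA_real_, dim = dims, dimnames = lev)
  arr[cbind(idx$condition, idx$tissue, idx$gene)] <- summary$mean
  if (anyNA(arr)) {
    miss <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop("design is incomplete; e.g. missing cell ",
         cell_label(lev[[1]][miss[1]], lev[[2]][miss[2]], lev[[3]][miss[3]]))
  }
  if (length(unique(summary$n)) != 1L)
    stop("unbalanced design: replicate count differs across cells ",
         "(only balanced designs are supported)")
  list(means = arr, n = summary$n[1])
}

#' Balanced-design sum of squares for a main effect or interaction
#'
#' Classical sums of squares on the observation scale for any subset of the
#' factors `condition`, `tissue`, `gene` of a balanced summary table: cell
#' means are weighted by the (constant) replicate count, and the SS of all
#' seven terms add up to the treatment SS.
#'
#' @param summary Balanced summary table (`condition, tissue, gene, mean, sd, n`).
#' @param term Character vector naming the factors of the term, e.g.
#'   `"gene"` for a main effect or `c("tissue", "gene")` for an interaction.
#' @return The term's sum of squares (numeric scalar).
#' @export
factorial_ss <- function(summary, term) {
  facs <- c("condition", "tissue", "gene")
  term <- unique(match.arg(term, facs, several.ok = TRUE))
  ca <- summary_cell_array(summary)
  arr <- ca$means
  dims <- dim(arr)
  which_term <- match(term, facs)
  # inclusion-exclusion over sub-terms: effect = sum_{B subseteq A} (-1)^{|A|-|B|} mean_B
  eff <- array(0, dim = dims[which_term])
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(which_term)))
  for (r in seq_len(nrow(subsets))) {
    keep <- which_term[unlist(subsets[r, ])]
    m <- if (length(keep)) apply(arr, keep, mean) else mean(arr)
    sgn <- (-1)^(length(which_term) - length(keep))
    if (length(keep)) {
      perm <- match(which_term, c(keep, setdiff(which_term, keep)))
      expanded <- array(m, dim = c(dims[keep], dims[setdiff(which_term, keep)]))
      eff <- eff + sgn * aperm(expanded, perm)
    } else {
      eff <- eff + sgn * m
    }
  }
  ca$n * prod(dims[-which_term]) * sum(eff^2)
}

#' Pooled within-cell error SS from per-cell standard deviations
#'
#' For sufficient-statistics input the replicate-level residual sum of
#' squares is recovered exactly as \eqn{\sum (n_i - 1) sd_i^2} with
#' \eqn{\sum (n_i - 1)} degrees of freedom.
#'
#' @param summary Summary table.
#' @return List with elements `ss` and `df`.
#' @export
error_ss_from_sd <- function(summary) {
  validate_summary_table(summary)
  list(ss = sum((summary$n - 1) * summary$sd^2),
       df = as.integer(sum(summary$n - 1)))
}

#' F test from mean squares
#'
#' @param ms_num,df_num Numerator mean square and its df.
#' @param ms_den,df_den Denominator mean square and its df.
#' @return List with the variance ratio `f` and the upper-tail `p` value.
#' @export
f_test <- function(ms_num, df_num, ms_den, df_den) {
  if (df_num <= 0 || df_den <= 0) stop("degrees of freedom must be positive")
  if (ms_den <= 0) stop("denominator mean square must be positive")
  f <- ms_num / ms_den
  list(f = f, p = stats::pf(f, df_num, df_den, lower.tail = FALSE))
}

group_ss <- function(y, idx, weight, grand) {
  m <- rowsum(y, idx)[, 1] / tabulate(idx)
  weight * sum((m - grand)^2)
}

#' Split-split-plot analysis of variance
#'
#' Three-tier randomized design with temperature (condition) on main plots,
#' tissue on sub-plots and gene on sub-sub-plots, replicated in complete
#' blocks. Each fixed term is tested against the error stratum of its own
#' plot level: condition against the main-plot error, tissue and
#' condition x tissue against the sub-plot error, and all gene terms against
#' the residual sub-sub-plot error. Blocks are a replication factor and get
#' no F test.
#'
#' @param table Long-format expression table, one observation per
#'   condition x tissue x gene x block combination (complete and balanced).
#' @return An `anova_table` with rows Blocks, Condition (temperature),
#'   Main-plot error, Tissue, Condition:Tissue, Sub-plot error, Gene,
#'   Condition:Gene, Tissue:Gene, Condition:Tissue:Gene, Sub-sub-plot error.
#' @export
split_split_plot_anova <- function(table) {
  validate_expression_table(table)
  fi <- factor(table$condition, levels = unique(table$condition))
  fh <- factor(table$tissue, levels = unique(table$tissue))
  fj <- factor(table$gene, levels = unique(table$gene))
  fk <- factor(table$block, levels = unique(table$block))
  t_ <- nlevels(fi); s_ <- nlevels(fh); g_ <- nlevels(fj); b_ <- nlevels(fk)
  if (nrow(table) != t_ * s_ * g_ * b_) {
    full <- expand.grid(condition = levels(fi), tissue = levels(fh),
                        gene = levels(fj), block = levels(fk))
    have <- paste(fi, fh, fj, fk)
    want <- paste(full$condition, full$tissue, full$gene, full$block)
    miss <- full[!(want %in% have), , drop = FALSE]
    stop("design is incomplete; missing ", nrow(miss), " cell(s), e.g. ",
         paste(utils::head(apply(miss, 1, paste, collapse = "/"), 3), collapse = "; "))
  }
  y <- table$expression
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)

  i <- as.integer(fi); h <- as.integer(fh); j <- as.integer(fj); k <- as.integer(fk)
  ss_blocks <- group_ss(y, k, t_ * s_ * g_, grand)
  ss_t  <- group_ss(y, i, b_ * s_ * g_, grand)
  ss_ik <- group_ss(y, (i - 1L) * b_ + k, s_ * g_, grand)
  ss_mp_err <- ss_ik - ss_t - ss_blocks
  ss_s  <- group_ss(y, h, b_ * t_ * g_, grand)
  ss_ih <- group_ss(y, (i - 1L) * s_ + h, b_ * g_, grand)
  ss_ts <- ss_ih - ss_t - ss_s
  ss_ihk <- group_ss(y, ((i - 1L) * s_ + (h - 1L)) * b_ + k, g_, grand)
  ss_sp_err <- ss_ihk - ss_blocks - ss_t - ss_mp_err - ss_s - ss_ts
  ss_g  <- group_ss(y, j, b_ * t_ * s_, grand)
  ss_ij <- group_ss(y, (i - 1L) * g_ + j, b_ * s_, grand)
  ss_tg <- ss_ij - ss_t - ss_g
  ss_hj <- group_ss(y, (h - 1L) * g_ + j, b_ * t_, grand)
  ss_sg <- ss_hj - ss_s - ss_g
  ss_ihj <- group_ss(y, ((i - 1L) * s_ + (h - 1L)) * g_ + j, b_, grand)
  ss_tsg <- ss_ihj - ss_t - ss_s - ss_g - ss_ts - ss_tg - ss_sg
  fitted_ss <- ss_blocks + ss_t + ss_mp_err + ss_s + ss_ts + ss_sp_err +
    ss_g + ss_tg + ss_sg + ss_tsg
  ss_ssp_err <- ss_total - fitted_ss
  clamp <- function(x) pmax(x, 0)

  df <- c(b_ - 1, t_ - 1, (b_ - 1) * (t_ - 1),
          s_ - 1, (t_ - 1) * (s_ - 1), t_ * (b_ - 1) * (s_ - 1),
          g_ - 1, (t_ - 1) * (g_ - 1), (s_ - 1) * (g_ - 1),
          (t_ - 1) * (s_ - 1) * (g_ - 1), t_ * s_ * (b_ - 1) * (g_ - 1))
  ss <- clamp(c(ss_blocks, ss_t, ss_mp_err, ss_s, ss_ts, ss_sp_err,
                ss_g, ss_tg, ss_sg, ss_tsg, ss_ssp_err))
  ms <- ss / df
  # error stratum index for each fixed term: 3 = main-plot, 6 = sub-plot, 11 = residual
  denom <- c(NA, 3, NA, 6, 6, NA, 11, 11, 11, 11, NA)
  f <- p <- rep(NA_real_, 11)
  for (r in which(!is.na(denom))) {
    if (ms[denom[r]] > 0) {  # degenerate zero-noise stratum: no test
      ft <- f_test(ms[r], df[r], ms[denom[r]], df[denom[r]])
      f[r] <- ft$f; p[r] <- ft$p
    }
  }
  new_anova_table(
    c("Blocks", "Condition", "Main-plot error", "Tissue", "Condition:Tissue",
      "Sub-plot error", "Gene", "Condition:Gene", "Tissue:Gene",
      "Condition:Tissue:Gene", "Sub-sub-plot error"),
    df, ss, ms, f, p)
}
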