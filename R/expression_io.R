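#' Relative expression by the 2^-ddCt method
#'
#' Converts quantitative PCR cycle thresholds (Ct) into a fold-change
#' relative to a reference gene and a calibrator sample:
#' \deqn{2^{-[(Ct_{target} - Ct_{ref}) - (Ct_{target,cal} - Ct_{ref,cal})]}}
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param ct_target Ct of the target gene in the sample of interest.
#' @param ct_ref Ct of the reference gene in the same sample.
#' @param ct_target_cal Ct of the target gene in the calibrator sample.
#' @param ct_ref_cal Ct of the reference gene in the calibrator sample.
#' @return Numeric fold-change, strictly positive.
#' @examples
#' relative_expression(17, 15, 20, 15) # ddCt = -3, fold-change 8
#' @export
relative_expression <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  args <- list(ct_target, ct_ref, ct_target_cal, ct_ref_cal)
  ok <- vapply(args, function(x) is.numeric(x) && all(is.finite(x)), logical(1))
  if (!all(ok))
    stop("all Ct values must be finite numbers")
  ddct <- (ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

exp_cols <- c("condition", "tissue", "gene", "block", "expression")
sum_cols <- c("condition", "tissue", "gene", "mean", "sd", "n")

validate_expression_table <- function(table) {
  if (!is.data.frame(table))
    stop("expression table must be a data.frame")
  missing <- setdiff(exp_cols, names(table))
  if (length(missing))
    stop("expression table is missing column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(table$expression) || any(!is.finite(table$expression)))
    stop("'expression' must be finite numeric")
  key <- interaction(table$condition, table$tissue, table$gene, table$block, drop = TRUE)
  if (anyDuplicated(key))
    stop("(condition, tissue, gene, block) combinations must be unique")
  invisible(table)
}

validate_summary_table <- function(summary) {
  if (!is.data.frame(summary))
    stop("summary table must be a data.frame")
  missing <- setdiff(sum_cols, names(summary))
  if (length(missing))
    stop("summary table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(summary$mean)) || any(!is.finite(summary$sd)))
    stop("'mean' and 'sd' must be finite numeric")
  if (any(summary$sd < 0)) stop("'sd' must be non-negative")
  if (any(summary$n < 2)) stop("every cell needs n >= 2")
  invisible(summary)
}

cell_label <- function(condition, tissue, gene) {
  paste0("(", condition, ", ", tissue, ", ", gene, ")")
}

#' Summarize replicate-level expression to sufficient statistics
#'
#' Collapses a long-format expression table to one row per
#' condition x tissue x gene cell carrying the sample mean, the sample
#' standard deviation (n - 1 denominator) and the replicate count. These
#' sufficient statistics drive every downstream analysis of the package,
#' so a table regenerated from them by [expand_summary()] summarizes back
#' to the identical summary.
#'
#' @param table Long-format data.frame with columns
#'   `condition, tissue, gene, block, expression`.
#' @return Data.frame with columns `condition, tissue, gene, mean, sd, n`.
#' @seealso [expand_summary()] for the inverse direction.
#' @export
summarize_expression <- function(table) {
  validate_expression_table(table)
  key <- interaction(table$condition, table$tissue, table$gene, drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  cells <- table[first, c("condition", "tissue", "gene")]
  idx <- match(key, key[first])
  n <- tabulate(idx, nbins = sum(first))
  if (any(n < 2)) {
    bad <- which(n < 2)[1L]
    stop("cell ", cell_label(cells$condition[bad], cells$tissue[bad], cells$gene[bad]),
         " has fewer than 2 replicates")
  }
  mean_ <- rowsum(table$expression, idx)[, 1] / n
  ss <- rowsum((table$expression - mean_[idx])^2, idx)[, 1]
  out <- data.frame(cells, mean = mean_, sd = sqrt(ss / (n - 1)), n = n,
                    row.names = NULL, check.names = FALSE)
  out[order(match(out$condition, unique(table$condition)),
            match(out$tissue, unique(table$tissue)),
            match(out$gene, unique(table$gene))), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Expand a summary table into exact pseudo-replicates
#'
#' Inverse of [summarize_expression()]: for each cell it emits `n` values
#' whose sample mean and sample SD equal the cell's summary exactly. Seeded
#' standard-normal draws are affinely adjusted to the target moments, so the
#' result is deterministic given `seed` and the global RNG state is left
#' untouched. A cell with `sd = 0` expands to `n` copies of its mean.
#'
#' @param summary Summary data.frame (`condition, tissue, gene, mean, sd, n`).
#' @param seed Integer seed controlling the (moment-constrained) draws.
#' @return Long-format expression table with a `block` replicate index.
#' @export
expand_summary <- function(summary, seed = 1L) {
  validate_summary_table(summary)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    n <- summary$n[i]
    if (summary$sd[i] == 0) {
      x <- rep(summary$mean[i], n)
    } else {
      z <- stats::rnorm(n)
      while (stats::sd(z) == 0) z <- stats::rnorm(n)  # degenerate draw guard
      x <- summary$mean[i] + (z - mean(z)) * summary$sd[i] / stats::sd(z)
    }
    data.frame(condition = summary$condition[i], tissue = summary$tissue[i],
               gene = summary$gene[i], block = seq_len(n), expression = x)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged cold-exposure expression summary for Takifugu rubripes
#'
#' Per-cell summary statistics (mean, SD, n = 3) of 2^-ddCt relative
#' expression for four cold-resistance genes (AFP1, CIRP, HMGB1, YB-1)
#' measured in nine tissues (brain, heart, intestine, kidney, liver, muscle,
#' spleen, skin, gonad) of tiger puffer held at four water temperatures
#' (18, 13, 8, 5 degrees C): 144 cells in all. Conditions are stored as
#' numeric degrees Celsius, sorted from the control temperature downwards.
#'
#' @return Summary data.frame (`condition, tissue, gene, mean, sd, n`).
#' @examples
#' tk <- load_takifugu_cold()
#' nrow(tk) # 144
#' @export
load_takifugu_cold <- function() {
  path <- system.file("extdata", "takifugu_cold_summary.csv",
                      package = "gxtissue", mustWork = TRUE)
  read_summary_csv(path)
}

#' Read/write the package's CSV formats
#'
#' Long format has header `condition,tissue,gene,block,expression`;
#' summary format has header `condition,tissue,gene,mean,sd,n`.
#' Both readers validate the table invariants on load.
#'
#' @param path File path.
#' @param table,summary Tables to write.
#' @return The validated data.frame (readers) or `path`, invisibly (writers).
#' @name expression_csv
NULL

#' @rdname expression_csv
#' @export
read_expression_csv <- function(path) {
  table <- utils::read.csv(path, check.names = FALSE)
  validate_expression_table(table)
  table
}

#' @rdname expression_csv
#' @export
write_expression_csv <- function(table, path) {
  validate_expression_table(table)
  utils::write.csv(table[exp_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname expression_csv
#' @export
read_summary_csv <- function(path) {
  summary <- utils::read.csv(path, check.names = FALSE)
  validate_summary_table(summary)
  summary
}

#' @rdname expression_csv
#' @export
write_summary_csv <- function(summary, path) {
  validate_summary_table(summary)
  utils::write.csv(summary[sum_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
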