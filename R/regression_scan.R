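#' Fit one expression-versus-temperature curve family
#'
#' Three candidate families describe how mean expression responds to water
#' temperature: a power law `y = a * x^b` (fitted as a linear regression of
#' log y on log x, then back-transformed) and raw-coefficient polynomials of
#' degree 2 and 3. The power family's r2 is reported in log space, the
#' polynomials' in response space.
#'
#' @param x Temperatures (degrees C).
#' @param y Mean expression at each temperature.
#' @param family `"power"`, `"poly2"` or `"poly3"`.
#' @return Object of class `regression_fit`: `family`, `coefficients`,
#'   `r2`, `n_points`, `fitted`.
#' @export
fit_family <- function(x, y, family = c("power", "poly2", "poly3")) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  npar <- c(power = 2, poly2 = 3, poly3 = 4)[[family]]
  if (length(x) < npar)
    stop("family '", family, "' needs at least ", npar, " points")
  r2_of <- function(fit, resp) {
    ss_tot <- sum((resp - mean(resp))^2)
    if (ss_tot == 0) return(1)  # constant response: any family fits it
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  if (family == "power") {
    if (any(x <= 0) || any(y <= 0))
      stop("power family requires strictly positive x and y")
    fit <- stats::lm(log(y) ~ log(x))
    co <- c(a = exp(unname(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
    r2 <- r2_of(fit, log(y))
    fitted <- co[["a"]] * x^co[["b"]]
  } else {
    deg <- if (family == "poly2") 2L else 3L
    fit <- stats::lm(y ~ stats::poly(x, deg, raw = TRUE))
    co <- rev(unname(stats::coef(fit)))  # highest degree first
    names(co) <- paste0("c", rev(seq_len(deg + 1)) - 1)
    r2 <- r2_of(fit, y)
    fitted <- unname(stats::fitted(fit))
  }
  structure(list(family = family, coefficients = co, r2 = r2,
                 n_points = length(x), fitted = fitted),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s fit on %d points, r2 = %.4f\n", x$family, x$n_points, x$r2))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Select the most parsimonious adequate curve family
#'
#' With four design points a cubic interpolates exactly, so selection cannot
#' be by raw fit alone. The rule: take the smallest family (power < poly2 <
#' poly3 by parameter count) whose r2 reaches `1 - tau`, preferring the
#' power family whenever its log-space r2 reaches that bar; the cubic is the
#' fallback. `tau` defaults to 0.01.
#'
#' @param x,y As in [fit_family()].
#' @param tau Adequacy slack on r2 (default 0.01).
#' @return Family label, one of `"power"`, `"poly2"`, `"poly3"`.
#' @export
select_family <- function(x, y, tau = 0.01) {
  if (length(x) < 3) stop("need at least 3 points to select a family")
  bar <- 1 - tau
  if (all(x > 0) && all(y > 0)) {
    if (fit_family(x, y, "power")$r2 >= bar) return("power")
  }
  if (fit_family(x, y, "poly2")$r2 >= bar) return("poly2")
  "poly3"
}

#' Curve-family scan over all gene x tissue series
#'
#' Fits every candidate family to the mean expression of each gene in each
#' tissue across the conditions of a summary table and records the selected
#' family under the parsimony rule of [select_family()].
#'
#' @param summary Summary table covering >= 3 conditions per series.
#' @param tau Passed to [select_family()].
#' @return Data.frame `gene, tissue, selected, r2_power, r2_poly2, r2_poly3`
#'   plus the fitted coefficients of the selected family (list column
#'   `coefficients`). Power r2 is `NA` where the family is inapplicable.
#' @export
regression_scan <- function(summary, tau = 0.01) {
  validate_summary_table(summary)
  genes <- unique(summary$gene)
  tissues <- unique(summary$tissue)
  rows <- list()
  for (g in genes) for (tt in tissues) {
    s <- summary[summary$gene == g & summary$tissue == tt, ]
    if (!nrow(s)) next
    x <- as.numeric(s$condition); y <- s$mean
    r2p <- if (all(x > 0) && all(y > 0)) fit_family(x, y, "power")$r2 else NA_real_
    sel <- select_family(x, y, tau)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, tissue = tt, selected = sel,
      r2_power = r2p,
      r2_poly2 = fit_family(x, y, "poly2")$r2,
      r2_poly3 = fit_family(x, y, "poly3")$r2,
      coefficients = I(list(fit_family(x, y, sel)$coefficients)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
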