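#' Double-logarithmic binding fit
#'
#' For static quenching by complex formation, the binding constant Kb and
#' stoichiometry n follow from the double-log linearization
#' \deqn{\log_{10}\frac{F_0 - F}{F} = \log_{10} K_b + n \log_{10} [Q]}
#' fitted by ordinary least squares with [Q] in mol/L, so Kb carries units
#' of M^-n. Points with F >= F0 (the log transform is undefined there) are
#' excluded and counted; the standard error of Kb is propagated from the
#' intercept's standard error by the delta method,
#' `kb_sd = kb * ln(10) * SE(intercept)`.
#'
#' @param series A [titration_series()].
#' @return An object of class `binding_result` with fields `kb` (M^-n),
#'   `n` (stoichiometry, slope), `kb_sd`, `r` (Pearson correlation),
#'   `temperature`, `n_points` (used), and `n_excluded`.
#' @export
double_log_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  F0 <- f0(series)
  nz <- series$ligand_conc > 0
  f <- series$intensity[nz]
  usable <- f < F0
  n_excluded <- sum(!usable)
  if (sum(usable) < 3L)
    stop(sprintf(
      "double_log_fit: only %d usable points with [Q] > 0 and F < F0 (need 3)",
      sum(usable)), call. = FALSE)
  q <- uM_to_M(series$ligand_conc[nz][usable])
  y <- log10((F0 - f[usable]) / f[usable])
  x <- log10(as.numeric(q))
  fit <- stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit))$coefficients
  kb <- 10^unname(co["(Intercept)", "Estimate"])
  structure(
    list(kb = kb,
         n = unname(co["x", "Estimate"]),
         kb_sd = kb * log(10) * unname(co["(Intercept)", "Std. Error"]),
         r = if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y),
         temperature = series$temperature,
         n_points = sum(usable),
         n_excluded = n_excluded,
         label = series$label),
    class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("Double-log binding fit%s at %g K\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$temperature))
  cat(sprintf("  Kb = %.4g +/- %.3g M^-n, n = %.3f (R = %.4f)\n",
              x$kb, x$kb_sd, x$n, x$r))
  if (x$n_excluded > 0L)
    cat(sprintf("  %d point(s) with F >= F0 excluded from the transform\n",
                x$n_excluded))
  invisible(x)
}
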