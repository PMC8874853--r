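#' Stern-Volmer fit of a quenching titration
#'
#' Fits the Stern-Volmer relation F0/F = 1 + Ksv [Q] by ordinary least
#' squares of F0/F on the quencher concentration in mol/L. The intercept is
#' fitted rather than constrained to 1; a deviation of the fitted intercept
#' from 1 beyond three standard errors is surfaced as a warning, as is any
#' point showing fluorescence enhancement (F >= F0) -- such points are
#' retained, not dropped. The bimolecular quenching constant is
#' kq = Ksv / tau0 with tau0 the unquenched fluorophore lifetime
#' (10^-8 s is the customary value for biopolymers).
#'
#' @param series A [titration_series()].
#' @param tau0 Fluorophore lifetime in seconds (default `1e-8`).
#' @return An object of class `quenching_result` with fields `ksv` (M^-1),
#'   `ksv_sd` (standard error of the slope), `intercept`, `r` (Pearson
#'   correlation of F0/F with [Q]), `kq` (M^-1 s^-1), `tau0`, `temperature`,
#'   `n_points`, and `enhancement_flagged`.
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8) {
  stopifnot(inherits(series, "titration_series"))
  if (!is.numeric(tau0) || length(tau0) != 1L || tau0 <= 0)
    stop("stern_volmer_fit: tau0 must be a single positive lifetime (s)",
         call. = FALSE)
  F0 <- f0(series)
  nz <- series$ligand_conc > 0
  if (sum(nz) < 3L)
    stop("stern_volmer_fit: need at least 3 points with [Q] > 0",
         call. = FALSE)
  f <- series$intensity[nz]
  enhanced <- f >= F0
  if (any(enhanced))
    warning(sprintf(
      "stern_volmer_fit: %d point(s) with F >= F0 (fluorescence enhancement) retained",
      sum(enhanced)), call. = FALSE)
  q <- uM_to_M(series$ligand_conc[nz])
  ratio <- F0 / f
  fit <- stats::lm(ratio ~ q)
  co <- suppressWarnings(summary(fit))$coefficients  # noise-free data trips
                                                     # summary.lm's perfect-fit
                                                     # warning
  ksv <- unname(co["q", "Estimate"])
  intercept <- unname(co["(Intercept)", "Estimate"])
  int_se <- unname(co["(Intercept)", "Std. Error"])
  if (is.finite(int_se) && int_se > 0 && abs(intercept - 1) > 3 * int_se &&
      abs(intercept - 1) > 1e-8)
    warning(sprintf(
      "stern_volmer_fit: intercept %.4g deviates from 1 by > 3 SE", intercept),
      call. = FALSE)
  structure(
    list(ksv = ksv,
         ksv_sd = unname(co["q", "Std. Error"]),
         intercept = intercept,
         r = if (stats::sd(ratio) == 0) NA_real_
             else stats::cor(as.numeric(q), ratio),
         kq = ksv / tau0,
         tau0 = tau0,
         temperature = series$temperature,
         n_points = sum(nz),
         enhancement_flagged = sum(enhanced),
         label = series$label),
    class = "quenching_result")
}

#' @export
print.quenching_result <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit%s at %g K\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$temperature))
  cat(sprintf("  Ksv = %.6g +/- %.3g M^-1 (intercept %.4g, R = %.4f)\n",
              x$ksv, x$ksv_sd, x$intercept, x$r))
  cat(sprintf("  kq  = %.4g M^-1 s^-1 (tau0 = %g s)\n", x$kq, x$tau0))
  invisible(x)
}

#' Classify the quenching mechanism
#'
#' Two independent diagnostics separate static (ground-state complex) from
#' dynamic (collisional) quenching:
#' \describe{
#'   \item{temperature trend}{Ksv strictly decreasing with rising temperature
#'     votes static (complex dissociates on heating); strictly increasing
#'     votes dynamic (faster diffusion). Needs >= 2 temperatures.}
#'   \item{kq magnitude}{Diffusion caps the collisional quenching constant
#'     near 2e10 M^-1 s^-1; kq above that for every temperature votes
#'     static, at or below it for every temperature votes dynamic.}
#' }
#' The label is `static` or `dynamic` when the applicable criteria agree (or
#' only one applies); conflicting votes give `ambiguous` with both outcomes
#' recorded in the evidence table.
#'
#' @param results A list of `quenching_result` objects (one or more
#'   temperatures, all sharing `tau0`).
#' @param kq_threshold Diffusion-limited ceiling for kq in M^-1 s^-1
#'   (default `2e10`).
#' @return An object of class `mechanism_call` with fields `label` (one of
#'   `"static"`, `"dynamic"`, `"ambiguous"`) and `evidence`, a data frame of
#'   (criterion, outcome) pairs.
#' @export
classify_mechanism <- function(results, kq_threshold = 2e10) {
  if (inherits(results, "quenching_result")) results <- list(results)
  if (length(results) == 0L)
    stop("classify_mechanism: no quenching results supplied", call. = FALSE)
  if (!all(vapply(results, inherits, logical(1L), "quenching_result")))
    stop("classify_mechanism: inputs must be quenching_result objects",
         call. = FALSE)
  tau0 <- vapply(results, `[[`, numeric(1L), "tau0")
  if (length(unique(tau0)) > 1L)
    stop("classify_mechanism: all results must share tau0", call. = FALSE)
  temps <- vapply(results, `[[`, numeric(1L), "temperature")
  ord <- order(temps)
  ksv <- vapply(results, `[[`, numeric(1L), "ksv")[ord]
  kq <- vapply(results, `[[`, numeric(1L), "kq")[ord]

  votes <- character(0L)
  evidence <- list()
  if (length(unique(temps)) >= 2L) {
    d <- diff(ksv)
    out <- if (all(d < 0)) "static"
           else if (all(d > 0)) "dynamic"
           else "inconclusive"
    if (out != "inconclusive") votes <- c(votes, out)
    evidence$temperature_trend <- sprintf(
      "Ksv %s with temperature -> %s",
      if (all(d < 0)) "strictly decreasing"
      else if (all(d > 0)) "strictly increasing" else "non-monotone", out)
  }
  out_b <- if (all(kq > kq_threshold)) "static"
           else if (all(kq <= kq_threshold)) "dynamic"
           else "inconclusive"
  if (out_b != "inconclusive") votes <- c(votes, out_b)
  evidence$kq_magnitude <- sprintf(
    "kq %s threshold %.3g M^-1 s^-1 -> %s",
    if (all(kq > kq_threshold)) "all above"
    else if (all(kq <= kq_threshold)) "all at or below" else "straddles",
    kq_threshold, out_b)

  label <- if (length(votes) == 0L) "ambiguous"
           else if (length(unique(votes)) == 1L) votes[1L]
           else "ambiguous"
  structure(
    list(label = label,
         evidence = data.frame(criterion = names(evidence),
                               outcome = unlist(evidence, use.names = FALSE),
                               stringsAsFactors = FALSE)),
    class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Quenching mechanism:", x$label, "\n")
  for (i in seq_len(nrow(x$evidence)))
    cat("  -", x$evidence$criterion[i], ":", x$evidence$outcome[i], "\n")
  invisible(x)
}

#' Total quenching percentage of a titration
#'
#' The percent drop in fluorescence from the unquenched intensity F0 to the
#' intensity at the highest quencher concentration:
#' 100 (F0 - F_last) / F0.
#'
#' @param series A [titration_series()].
#' @return Quenching percentage (may be negative for net enhancement).
#' @export
quenching_percentage <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  F0 <- f0(series)
  f_last <- series$intensity[length(series$intensity)]
  100 * (F0 - f_last) / F0
}
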