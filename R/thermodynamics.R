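# Gas constant, J mol^-1 K^-1
.R_GAS <- 8.314

#' Gibbs free energy from enthalpy and entropy
#'
#' Evaluates the identity \eqn{\Delta G^\circ = \Delta H^\circ - T \Delta
#' S^\circ} with the unit mix conventional for binding tables: enthalpy and
#' the returned free energy in kJ/mol, entropy in J/(mol K).
#'
#' @param delta_h Enthalpy change in kJ/mol.
#' @param delta_s Entropy change in J/(mol K).
#' @param t Temperature in K (> 0). Vectorized.
#' @return Gibbs free energy in kJ/mol.
#' @export
gibbs <- function(delta_h, delta_s, t) {
  if (any(t <= 0)) stop("gibbs: temperature must be positive", call. = FALSE)
  delta_h - t * delta_s / 1000
}

#' Classify the dominant interaction forces from thermodynamic signs
#'
#' Ross-rule mapping of the signs of the binding enthalpy and entropy to the
#' dominant non-covalent force: both negative indicates van der Waals
#' contacts and hydrogen bonding, both positive hydrophobic interactions,
#' negative enthalpy with positive entropy electrostatic interactions. Also
#' reports whether the binding is enthalpy- or entropy-driven and whether it
#' is spontaneous (Gibbs energy negative) at the reference temperature.
#'
#' @param delta_h Enthalpy change in kJ/mol.
#' @param delta_s Entropy change in J/(mol K).
#' @param t_ref Reference temperature in K for the driving/spontaneity
#'   calls (default 298).
#' @return A list with `force_label`, `driving` (one of
#'   `"enthalpy-driven"`, `"entropy-driven"`, `"both"`), `spontaneous`
#'   (logical), and `delta_g_ref` (kJ/mol at `t_ref`).
#' @export
classify_forces <- function(delta_h, delta_s, t_ref = 298) {
  force_label <-
    if (delta_h < 0 && delta_s < 0) "van der Waals + hydrogen bonding"
    else if (delta_h > 0 && delta_s > 0) "hydrophobic"
    else if (delta_h < 0 && delta_s > 0) "electrostatic"
    else "unfavorable/other"
  driving <-
    if (delta_h < 0 && t_ref * delta_s < 0) "enthalpy-driven"
    else if (delta_h >= 0 && delta_s > 0) "entropy-driven"
    else "both"
  dg <- gibbs(delta_h, delta_s, t_ref)
  list(force_label = force_label, driving = driving,
       spontaneous = dg < 0, delta_g_ref = dg)
}

#' van't Hoff analysis of temperature-dependent binding constants
#'
#' Fits \eqn{\ln K_b = -\Delta H^\circ/(RT) + \Delta S^\circ/R} by ordinary
#' least squares of ln(Kb) on 1/T: the enthalpy is -slope * R and the
#' entropy intercept * R, with R = 8.314 J/(mol K). The enthalpy is assumed
#' temperature-independent over the studied range (linear van't Hoff).
#' Gibbs energies are evaluated at each requested temperature via
#' [gibbs()], and the force classification at 298 K via
#' [classify_forces()] is attached.
#'
#' @param temperatures Temperatures in K (>= 2 distinct values).
#' @param kb Binding constants (M^-1, > 0), one per temperature.
#' @param eval_temps Temperatures (K) at which to evaluate Gibbs energy;
#'   defaults to `temperatures`.
#' @return An object of class `thermo_result` with fields `delta_h`
#'   (kJ/mol), `delta_s` (J/(mol K)), `delta_g` (named vector, kJ/mol, one
#'   per eval temperature), `r` (Pearson correlation of ln Kb with 1/T),
#'   `force_label`, `driving`, `spontaneous`, and the input `temperatures`.
#' @export
vant_hoff_fit <- function(temperatures, kb, eval_temps = temperatures) {
  temperatures <- as.numeric(temperatures)
  kb <- as.numeric(kb)
  if (length(temperatures) != length(kb))
    stop("vant_hoff_fit: temperatures and kb lengths differ", call. = FALSE)
  if (any(kb <= 0))
    stop("vant_hoff_fit: binding constants must be positive", call. = FALSE)
  if (any(temperatures <= 0))
    stop("vant_hoff_fit: temperatures must be positive (K)", call. = FALSE)
  n_distinct <- length(unique(temperatures))
  if (n_distinct < 2L)
    stop("vant_hoff_fit: need at least 2 distinct temperatures",
         call. = FALSE)
  if (n_distinct < length(temperatures))
    warning("vant_hoff_fit: duplicate temperatures present; fit proceeds",
            call. = FALSE)
  x <- 1 / temperatures
  y <- log(kb)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  delta_h <- -slope * .R_GAS / 1000   # kJ/mol
  delta_s <- intercept * .R_GAS       # J/(mol K)
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  dg <- gibbs(delta_h, delta_s, eval_temps)
  names(dg) <- as.character(eval_temps)
  forces <- classify_forces(delta_h, delta_s)
  structure(
    list(delta_h = delta_h, delta_s = delta_s, delta_g = dg,
         r = r,
         force_label = forces$force_label, driving = forces$driving,
         spontaneous = forces$spontaneous,
         temperatures = temperatures),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("van't Hoff analysis\n")
  cat(sprintf("  dH = %.4g kJ/mol, dS = %.4g J/(mol K), R(fit) = %.4f\n",
              x$delta_h, x$delta_s, x$r))
  for (tt in names(x$delta_g))
    cat(sprintf("  dG(%s K) = %.4g kJ/mol\n", tt, x$delta_g[[tt]]))
  cat(sprintf("  forces: %s; %s; %s\n", x$force_label, x$driving,
              if (x$spontaneous) "spontaneous" else "non-spontaneous"))
  invisible(x)
}
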