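# Synthetic titrations, spectra and EEMs with known ground truth.
#
# The generator produces data consistent with the linearized analysis
# equations (Stern-Volmer line for dynamic quenching, double-log isotherm
# for static quenching), not a full mass-balance binding simulation, so
# parameter-recovery tests are exact at zero noise. Defaults emulate a
# serum-albumin titration: protein 1.5 uM, ligand 0-27.5 uM in 11 steps.

#' Ground truth for a synthetic titration
#'
#' @param mechanism `"static"` (complex formation; binding constant and
#'   stoichiometry drive the signal) or `"dynamic"` (collisional;
#'   Stern-Volmer constant drives it).
#' @param kb Binding constant in M^-1 (static mechanism).
#' @param n Binding stoichiometry (static mechanism).
#' @param ksv Stern-Volmer constant in M^-1 at 298 K (dynamic mechanism).
#' @param competitor_k Competitor binding constant in M^-1 (0 = none).
#' @param competitor_conc Competitor concentration in uM.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   noise (0 = noise-free; 0.01 approximates shot/gain noise of a
#'   benchtop spectrofluorometer).
#' @param ife Optional list `(a_ex=, a_em=)` of absorbances applied in
#'   reverse to emulate the inner filter effect (scalars or per-point).
#' @param seed Integer RNG seed; identical seeds give identical series.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(mechanism = c("static", "dynamic"),
                         kb = 2.07e4, n = 1, ksv = 2e4,
                         competitor_k = 0, competitor_conc = 0,
                         noise_cv = 0, ife = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(kb > 0, n > 0, ksv > 0, competitor_k >= 0,
            competitor_conc >= 0, noise_cv >= 0)
  structure(list(mechanism = mechanism, kb = kb, n = n, ksv = ksv,
                 competitor_k = competitor_k,
                 competitor_conc = competitor_conc,
                 noise_cv = noise_cv, ife = ife, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Apparent binding constant under competitive attenuation
#'
#' Classical competitive inhibition: a competitor at concentration `[C]`
#' (uM) with affinity `Kc` (M^-1) reduces the apparent binding constant to
#' `kb / (1 + Kc [C])`.
#'
#' @param kb Intrinsic binding constant, M^-1.
#' @param competitor_k Competitor binding constant, M^-1.
#' @param competitor_conc Competitor concentration, uM.
#' @return Apparent binding constant, M^-1.
#' @export
apparent_kb <- function(kb, competitor_k, competitor_conc) {
  kb / (1 + competitor_k * competitor_conc * 1e-6)
}

# Temperature coefficient for the dynamic-quenching Ksv: collisional
# quenching accelerates with diffusion, here +1%/K above 298 K.
.KSV_TEMP_COEF <- 0.01

#' Generate a synthetic quenching titration
#'
#' Static mechanism: `(F0 - F)/F = kb_app [Q]^n` with the apparent binding
#' constant attenuated by any competitor (see [apparent_kb()]), so
#' `F = f0 / (1 + kb_app [Q]^n)`. Dynamic mechanism:
#' `F = f0 / (1 + Ksv(T) [Q])` with Ksv increasing by 1%/K above 298 K.
#' Multiplicative Gaussian noise with the truth's CV is applied under the
#' truth's seed; when the truth carries inner-filter absorbances, the
#' attenuation is applied in reverse (`observed = true / exp((A_ex +
#' A_em)/2)`) so that [correct_inner_filter()] recovers the true signal.
#'
#' @param truth A [ground_truth()].
#' @param conc_grid Quencher concentrations in uM, starting at 0; default
#'   0-27.5 uM in 11 steps.
#' @param f0 Unquenched intensity (default 1000).
#' @param temperature Temperature in K (default 298).
#' @param label Series label.
#' @return A [titration_series()]; the generating [ground_truth()] is
#'   attached as attribute `"truth"`.
#' @export
generate_titration <- function(truth, conc_grid = seq(0, 27.5, length.out = 11),
                               f0 = 1000, temperature = 298,
                               label = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(conc_grid < 0))
    stop("generate_titration: concentrations must be non-negative",
         call. = FALSE)
  if (conc_grid[1L] != 0)
    stop("generate_titration: grid must start at 0", call. = FALSE)
  q <- conc_grid * 1e-6  # mol/L
  f_true <- if (truth$mechanism == "static") {
    kb_app <- apparent_kb(truth$kb, truth$competitor_k,
                          truth$competitor_conc)
    f0 / (1 + kb_app * q^truth$n)
  } else {
    ksv_t <- truth$ksv * (1 + .KSV_TEMP_COEF * (temperature - 298))
    f0 / (1 + ksv_t * q)
  }
  f <- f_true
  if (truth$noise_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(truth$seed)
    f <- f * (1 + truth$noise_cv * stats::rnorm(length(f)))
    if (any(f <= 0))
      stop("generate_titration: noise produced non-positive intensity; ",
           "reduce noise_cv", call. = FALSE)
  }
  a_ex <- a_em <- NULL
  if (!is.null(truth$ife)) {
    a_ex <- rep_len(truth$ife$a_ex, length(q))
    a_em <- rep_len(truth$ife$a_em, length(q))
    f <- f / exp((a_ex + a_em) / 2)  # observed, pre-correction
  }
  series <- titration_series(
    ligand_conc = conc_grid, intensity_obs = f, temperature = temperature,
    label = label, protein_conc = 1.5, a_ex = a_ex, a_em = a_em,
    competitor = if (truth$competitor_conc > 0)
      list(name = "competitor", conc_uM = truth$competitor_conc) else NULL)
  attr(series, "truth") <- truth
  series
}

#' Generate a van't Hoff titration set
#'
#' Binding constants follow `K(T) = exp(-dH*1000/(R T) + dS/R)` with
#' R = 8.314 J/(mol K); one static-quenching titration is generated per
#' temperature with that K as its binding constant.
#'
#' @param delta_h Enthalpy change in kJ/mol.
#' @param delta_s Entropy change in J/(mol K).
#' @param temps Distinct temperatures in K.
#' @param n Binding stoichiometry (default 1).
#' @param noise_cv Multiplicative noise CV (default 0).
#' @param seed Base seed; temperature i uses `seed + i`.
#' @param conc_grid,f0 Passed to [generate_titration()].
#' @return A list with one element per temperature, each a list with
#'   `series` (the [titration_series()]) and `kb` (the true K(T)).
#' @export
generate_vant_hoff_set <- function(delta_h, delta_s, temps, n = 1,
                                   noise_cv = 0, seed = 1L,
                                   conc_grid = seq(0, 27.5, length.out = 11),
                                   f0 = 1000) {
  if (anyDuplicated(temps))
    stop("generate_vant_hoff_set: temperatures must be distinct",
         call. = FALSE)
  lapply(seq_along(temps), function(i) {
    t_i <- temps[i]
    k_t <- exp(-delta_h * 1000 / (.R_GAS * t_i) + delta_s / .R_GAS)
    truth <- ground_truth("static", kb = k_t, n = n, noise_cv = noise_cv,
                          seed = seed + i)
    list(series = generate_titration(truth, conc_grid = conc_grid, f0 = f0,
                                     temperature = t_i,
                                     label = sprintf("synthetic %g K", t_i)),
         kb = k_t)
  })
}

#' Generate a synthetic free/bound spectrum or EEM pair
#'
#' Emission pair: a Gaussian band on a 1-nm grid for the free fluorophore,
#' and a bound-state copy shifted by `shift_nm` and scaled by `damping`.
#' EEM pair: a sum of separable excitation x emission Gaussian peaks (by
#' default the protein Peak I at (280, 340) nm and Peak II at (230, 330)
#' nm) plus Rayleigh (em = ex) and second-order (em = 2 ex) scattering
#' ridges; the bound EEM has both fluorescence peaks scaled by `damping`
#' while the scattering ridges are unchanged.
#'
#' @param kind `"emission"` or `"eem"`.
#' @param peak_nm Emission peak center in nm (emission kind).
#' @param width_nm Gaussian standard deviation in nm.
#' @param amplitude Peak intensity of the free spectrum.
#' @param shift_nm Peak displacement of the bound spectrum (positive =
#'   redshift).
#' @param damping Intensity scale factor of the bound state (<= 1 for
#'   quenching).
#' @param grid Wavelength grid (emission kind); default 300-500 nm, 1 nm.
#' @param ex_grid,em_grid EEM grids; default 200-350 / 250-550 nm, 5 nm.
#' @param eem_peaks_at List of `(ex, em, amplitude)` peak definitions for
#'   the EEM kind.
#' @param eem_width_nm Gaussian standard deviation of the EEM peaks in nm;
#'   narrower than the emission default so the two protein peaks stay
#'   resolved on the excitation axis.
#' @param ridge_amplitude Scattering-ridge intensity (EEM kind).
#' @return A list with elements `free` and `bound`, each an
#'   [emission_spectrum()] or [eem()] according to `kind`.
#' @export
generate_spectra <- function(kind = c("emission", "eem"),
                             peak_nm = 340, width_nm = 25, amplitude = 1000,
                             shift_nm = 0, damping = 1,
                             grid = 300:500,
                             ex_grid = seq(200, 350, by = 5),
                             em_grid = seq(250, 550, by = 5),
                             eem_peaks_at = list(
                               list(ex = 280, em = 340, amplitude = 1000),
                               list(ex = 230, em = 330, amplitude = 600)),
                             eem_width_nm = 15,
                             ridge_amplitude = 200) {
  kind <- match.arg(kind)
  stopifnot(width_nm > 0)
  if (kind == "emission") {
    gauss <- function(center, amp)
      amp * exp(-(grid - center)^2 / (2 * width_nm^2))
    return(list(
      free = emission_spectrum(grid, gauss(peak_nm, amplitude)),
      bound = emission_spectrum(grid,
                                gauss(peak_nm + shift_nm,
                                      amplitude * damping))))
  }
  build <- function(scale) {
    m <- matrix(0, length(ex_grid), length(em_grid))
    for (p in eem_peaks_at)
      m <- m + scale * p$amplitude *
        outer(exp(-(ex_grid - p$ex)^2 / (2 * eem_width_nm^2)),
              exp(-(em_grid - p$em)^2 / (2 * eem_width_nm^2)))
    ridge <- function(k)
      ridge_amplitude * outer(ex_grid, em_grid,
                              function(a, b) exp(-(b - k * a)^2 / (2 * 3^2)))
    m <- m + ridge(1) + ridge(2)
    eem(ex_grid, em_grid, m)
  }
  list(free = build(1), bound = build(damping))
}
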