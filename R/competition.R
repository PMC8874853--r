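#' Compare binary and ternary binding systems
#'
#' Quantifies how a fixed-concentration competitor changes the quenching and
#' binding of a protein-ligand pair: the fold change in binding constant
#' (binary / ternary), the change in Stern-Volmer constant, and the change
#' in total quenching percentage. The interpretation text states the
#' direction of the effect and flags the characteristic displacement
#' signature where Ksv rises (the ligand becomes more accessible to the
#' protein surface) while Kb falls (specific binding is out-competed).
#'
#' @param binary A list with components `quenching` (a
#'   [stern_volmer_fit()] result), `binding` (a [double_log_fit()] result),
#'   and `series` (the underlying [titration_series()]).
#' @param ternary Same structure for the system with competitor present;
#'   must share the binary system's temperature.
#' @return An object of class `competition_report` with fields `kb_binary`,
#'   `kb_ternary`, `fold_change` (kb_binary / kb_ternary), `ksv_binary`,
#'   `ksv_ternary`, `quench_pct_binary`, `quench_pct_ternary`,
#'   `quench_pct_delta` (ternary - binary), and `interpretation`.
#' @export
compare_systems <- function(binary, ternary) {
  for (sys in list(binary, ternary)) {
    if (!is.list(sys) || !inherits(sys$quenching, "quenching_result") ||
        !inherits(sys$binding, "binding_result") ||
        !inherits(sys$series, "titration_series"))
      stop("compare_systems: each system needs $quenching, $binding, $series",
           call. = FALSE)
  }
  if (binary$quenching$temperature != ternary$quenching$temperature)
    stop("compare_systems: binary and ternary temperatures differ",
         call. = FALSE)
  kb_b <- binary$binding$kb
  kb_t <- ternary$binding$kb
  ksv_b <- binary$quenching$ksv
  ksv_t <- ternary$quenching$ksv
  qp_b <- quenching_percentage(binary$series)
  qp_t <- quenching_percentage(ternary$series)
  fold <- kb_b / kb_t

  interpretation <-
    if (isTRUE(all.equal(fold, 1)) && isTRUE(all.equal(qp_t, qp_b)))
      "no effect: competitor leaves binding and quenching unchanged"
    else if (fold > 1)
      sprintf("competitor reduces binding (Kb falls %.3g-fold)", fold)
    else
      sprintf("competitor increases binding (Kb rises %.3g-fold)", 1 / fold)
  if (ksv_t > ksv_b && kb_t < kb_b)
    interpretation <- paste0(
      interpretation,
      "; Ksv rises while Kb falls (increased ligand accessibility with ",
      "displaced specific binding)")
  structure(
    list(kb_binary = kb_b, kb_ternary = kb_t, fold_change = fold,
         ksv_binary = ksv_b, ksv_ternary = ksv_t,
         quench_pct_binary = qp_b, quench_pct_ternary = qp_t,
         quench_pct_delta = qp_t - qp_b,
         temperature = binary$quenching$temperature,
         interpretation = interpretation),
    class = "competition_report")
}

#' @export
print.competition_report <- function(x, ...) {
  cat(sprintf("Binary vs ternary comparison at %g K\n", x$temperature))
  cat(sprintf("  Kb:  %.4g -> %.4g (fold change %.4g)\n",
              x$kb_binary, x$kb_ternary, x$fold_change))
  cat(sprintf("  Ksv: %.4g -> %.4g M^-1\n", x$ksv_binary, x$ksv_ternary))
  cat(sprintf("  quenching: %.3g%% -> %.3g%% (delta %+.3g%%)\n",
              x$quench_pct_binary, x$quench_pct_ternary,
              x$quench_pct_delta))
  cat(" ", x$interpretation, "\n")
  invisible(x)
}

#' Infer the binding site from site-marker displacement
#'
#' Site markers are drugs with known, site-specific binding on serum
#' albumin (classically phenylbutazone for Sudlow Site I, ibuprofen for
#' Site II). A marker that substantially lowers the apparent binding
#' constant of the study ligand implicates its own site. The relative
#' change |Kb_marker - Kb_unmarked| / Kb_unmarked is computed per marker;
#' a site is assigned only when exactly one marker's effect exceeds the
#' threshold. Zero or several markers above threshold give
#' `"undetermined"` with the full evidence retained.
#'
#' @param kb_unmarked Binding constant without any marker (M^-1, > 0).
#' @param kb_by_marker Named numeric vector of binding constants in the
#'   presence of each marker.
#' @param marker_sites Named character vector mapping marker name to site
#'   label (e.g. `c(phenylbutazone = "Site I", ibuprofen = "Site II")`).
#' @param threshold Relative change above which a marker counts as
#'   influential (default 0.30).
#' @return An object of class `site_assignment` with fields `site` (a site
#'   label or `"undetermined"`) and `marker_effects` (named numeric vector
#'   of relative Kb changes).
#' @export
site_marker_inference <- function(kb_unmarked, kb_by_marker, marker_sites,
                                  threshold = 0.30) {
  if (!is.numeric(kb_unmarked) || kb_unmarked <= 0)
    stop("site_marker_inference: kb_unmarked must be positive", call. = FALSE)
  if (length(kb_by_marker) < 1L || is.null(names(kb_by_marker)))
    stop("site_marker_inference: kb_by_marker must be a named vector with ",
         ">= 1 marker", call. = FALSE)
  if (any(kb_by_marker <= 0))
    stop("site_marker_inference: marker Kb values must be positive",
         call. = FALSE)
  unknown <- setdiff(names(kb_by_marker), names(marker_sites))
  if (length(unknown))
    stop("site_marker_inference: no site mapping for marker(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  effects <- abs(kb_by_marker - kb_unmarked) / kb_unmarked
  above <- names(effects)[effects > threshold]
  site <- if (length(above) == 1L) unname(marker_sites[[above]])
          else "undetermined"
  structure(
    list(site = site, marker_effects = effects,
         markers_above_threshold = above, threshold = threshold),
    class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat("Site assignment:", x$site, "\n")
  for (m in names(x$marker_effects))
    cat(sprintf("  %s: relative Kb change %.3g%s\n", m, x$marker_effects[[m]],
                if (m %in% x$markers_above_threshold)
                  sprintf(" (> %.2g)", x$threshold) else ""))
  invisible(x)
}
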