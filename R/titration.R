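#' Correct fluorescence intensity for the inner filter effect
#'
#' Reabsorption of exciting and emitted light attenuates the measured
#' fluorescence when the sample absorbs appreciably at the excitation or
#' emission wavelength. The multiplicative correction
#' \deqn{F_{cor} = F_{obs} \exp\{(A_{ex} + A_{em})/2\}}
#' recovers the intensity that would have been observed in an optically
#' dilute sample.
#'
#' @param f_obs Observed fluorescence intensity (arbitrary units, > 0).
#' @param a_ex Absorbance at the excitation wavelength (dimensionless, >= 0).
#' @param a_em Absorbance at the emission wavelength (dimensionless, >= 0).
#' @return Corrected intensity, always `>= f_obs`. Vectorized over all
#'   arguments.
#' @examples
#' correct_inner_filter(100, 0.1, 0.1)  # 100 * exp(0.1)
#' @export
correct_inner_filter <- function(f_obs, a_ex, a_em) {
  if (!is.numeric(f_obs) || !is.numeric(a_ex) || !is.numeric(a_em))
    stop("correct_inner_filter: all arguments must be numeric", call. = FALSE)
  if (anyNA(f_obs) || anyNA(a_ex) || anyNA(a_em))
    stop("correct_inner_filter: NA values are not allowed", call. = FALSE)
  if (any(f_obs <= 0))
    stop("correct_inner_filter: observed intensity must be positive",
         call. = FALSE)
  if (any(a_ex < 0) || any(a_em < 0))
    stop("correct_inner_filter: absorbances must be non-negative",
         call. = FALSE)
  f_obs * exp((a_ex + a_em) / 2)
}

#' Construct a titration series
#'
#' One protein + ligand fluorescence titration at a single temperature: an
#' ordered ligand (quencher) concentration grid starting at zero, the
#' fluorescence intensity at the emission peak for each point, and optional
#' per-point absorbances at the excitation and emission wavelengths. The
#' intensity at zero quencher defines F0. When both absorbance columns are
#' supplied the inner-filter correction is applied on construction and
#' `ife_applied` is set; fits always use the corrected intensities.
#'
#' Concentrations are stored in micromolar (the usual reporting unit for
#' serum-albumin titrations) and converted to mol/L exactly once inside the
#' fitting routines, so fitted constants carry units of M^-1.
#'
#' @param ligand_conc Quencher concentrations in uM; strictly increasing,
#'   non-negative, first entry 0.
#' @param intensity_obs Observed fluorescence per point (positive).
#' @param temperature Temperature in K.
#' @param label Free-text series label.
#' @param protein_conc Protein concentration in uM (metadata; default NA).
#' @param a_ex,a_em Optional per-point absorbances (both or neither).
#' @param competitor Optional list with elements `name` and `conc_uM`
#'   describing a fixed-concentration second ligand (ternary system).
#' @return An object of class `titration_series` with fields
#'   `ligand_conc` (uM), `intensity_obs`, `intensity` (IFE-corrected when
#'   absorbances present, otherwise equal to `intensity_obs`), `a_ex`,
#'   `a_em`, `temperature`, `label`, `protein_conc`, `competitor`, and
#'   `ife_applied`.
#' @export
titration_series <- function(ligand_conc, intensity_obs, temperature,
                             label = "", protein_conc = NA_real_,
                             a_ex = NULL, a_em = NULL, competitor = NULL) {
  ligand_conc <- as.numeric(ligand_conc)
  intensity_obs <- as.numeric(intensity_obs)
  n <- length(ligand_conc)
  if (n < 2L)
    stop("titration_series: need at least two titration points", call. = FALSE)
  if (length(intensity_obs) != n)
    stop("titration_series: ligand_conc and intensity_obs lengths differ",
         call. = FALSE)
  if (anyNA(ligand_conc) || anyNA(intensity_obs))
    stop("titration_series: NA values are not allowed", call. = FALSE)
  if (ligand_conc[1L] != 0)
    stop("titration_series: first concentration must be 0 (defines F0)",
         call. = FALSE)
  if (any(diff(ligand_conc) <= 0))
    stop("titration_series: concentrations must be strictly increasing",
         call. = FALSE)
  if (any(intensity_obs <= 0))
    stop("titration_series: intensities must be strictly positive",
         call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0)
    stop("titration_series: temperature must be a single positive value (K)",
         call. = FALSE)
  has_a <- !is.null(a_ex) || !is.null(a_em)
  if (has_a) {
    if (is.null(a_ex) || is.null(a_em))
      stop("titration_series: supply both a_ex and a_em or neither",
           call. = FALSE)
    a_ex <- as.numeric(a_ex); a_em <- as.numeric(a_em)
    if (length(a_ex) != n || length(a_em) != n)
      stop("titration_series: absorbance vectors must match series length",
           call. = FALSE)
    intensity <- correct_inner_filter(intensity_obs, a_ex, a_em)
  } else {
    a_ex <- NULL; a_em <- NULL
    intensity <- intensity_obs
  }
  if (!is.null(competitor)) {
    if (!is.list(competitor) || is.null(competitor$name) ||
        is.null(competitor$conc_uM))
      stop("titration_series: competitor must be list(name=, conc_uM=)",
           call. = FALSE)
  }
  structure(
    list(label = label, protein_conc = protein_conc,
         ligand_conc = ligand_conc, intensity_obs = intensity_obs,
         intensity = intensity, a_ex = a_ex, a_em = a_em,
         temperature = temperature, competitor = competitor,
         ife_applied = has_a),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series%s: %d points, [Q] %.2f-%.2f uM, T = %g K\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$ligand_conc), min(x$ligand_conc), max(x$ligand_conc),
              x$temperature))
  cat(sprintf("  F0 = %.4g; inner-filter correction %s\n",
              x$intensity[1L],
              if (x$ife_applied) "applied" else "not applied"))
  if (!is.null(x$competitor))
    cat(sprintf("  competitor: %s at %g uM\n", x$competitor$name,
                x$competitor$conc_uM))
  invisible(x)
}

#' Unquenched reference intensity of a series
#'
#' @param series A [titration_series()].
#' @return F0, the (corrected) intensity at zero quencher.
#' @export
f0 <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  series$intensity[1L]
}

# Convert a uM concentration vector to mol/L, exactly once. The returned
# vector carries attr(unit) = "M"; converting an already-converted vector is
# an error so double conversion cannot pass silently.
uM_to_M <- function(conc) {
  if (identical(attr(conc, "unit"), "M"))
    stop("uM_to_M: concentrations already converted to mol/L", call. = FALSE)
  structure(conc * 1e-6, unit = "M")
}

#' Read a titration series from CSV
#'
#' Expected header: `conc_uM,F_obs` with optional `A_ex,A_em` absorbance
#' columns. Lines starting with `#` are comments. Rows are sorted by
#' concentration. Metadata (temperature, label, protein concentration,
#' competitor) can be passed as arguments or placed in a YAML sidecar file
#' `<path>.yaml`; explicit arguments override the sidecar.
#'
#' @param path Path to the CSV file.
#' @param temperature Temperature in K (required here or in the sidecar).
#' @param label Series label; defaults to the file name.
#' @param protein_conc Protein concentration in uM.
#' @param competitor Optional `list(name=, conc_uM=)`.
#' @return A validated [titration_series()]; the inner-filter correction is
#'   applied when absorbance columns are present.
#' @export
read_titration_csv <- function(path, temperature = NULL, label = NULL,
                               protein_conc = NULL, competitor = NULL) {
  if (!file.exists(path))
    stop("read_titration_csv: file not found: ", path, call. = FALSE)
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  if (is.null(temperature)) temperature <- meta$temperature
  if (is.null(label)) label <- if (!is.null(meta$label)) meta$label
                               else basename(path)
  if (is.null(protein_conc))
    protein_conc <- if (!is.null(meta$protein_conc)) meta$protein_conc
                    else NA_real_
  if (is.null(competitor)) competitor <- meta$competitor
  if (is.null(temperature))
    stop("read_titration_csv: temperature (K) missing; pass it or provide ",
         "a YAML sidecar", call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "character",
                        strip.white = TRUE, check.names = TRUE)
  required <- c("conc_uM", "F_obs")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("read_titration_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) || anyNA(v))
      stop(sprintf("read_titration_csv: non-numeric value in column '%s', row %d",
                   col, if (length(bad)) bad[1L] else which(is.na(v))[1L]),
           call. = FALSE)
    v
  }
  conc <- num("conc_uM")
  dup <- which(duplicated(conc))
  if (length(dup))
    stop(sprintf("read_titration_csv: duplicate concentration %g uM at row %d",
                 conc[dup[1L]], dup[1L]), call. = FALSE)
  ord <- order(conc)
  has_a <- all(c("A_ex", "A_em") %in% names(df))
  titration_series(
    ligand_conc = conc[ord],
    intensity_obs = num("F_obs")[ord],
    temperature = temperature, label = label, protein_conc = protein_conc,
    a_ex = if (has_a) num("A_ex")[ord] else NULL,
    a_em = if (has_a) num("A_em")[ord] else NULL,
    competitor = competitor)
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_csv()]: writes `conc_uM,F_obs[,A_ex,A_em]`
#' at full precision so a read-write-read cycle is lossless.
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(conc_uM = series$ligand_conc,
                   F_obs = series$intensity_obs)
  if (series$ife_applied) {
    df$A_ex <- series$a_ex
    df$A_em <- series$a_em
  }
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c(paste(names(df), collapse = ","),
             apply(df, 1L, function(r) paste(fmt(as.numeric(r)),
                                             collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
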