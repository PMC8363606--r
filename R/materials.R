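#' @title Constitutive models and plaque scoring
#' @description Hyperelastic reduced-polynomial models for the arterial wall
#'   and five plaque classes, Neo-Hookean silicone for bench phantoms, alloy
#'   elastoplasticity for stent platforms, balloon compliance classes, and the
#'   quarter-step plaque scoring system that maps OCT tissue composition to a
#'   stress-strain curve.
#' @name materials
NULL

#' Reduced-polynomial hyperelastic coefficient set
#'
#' Strain-energy density W = sum_i Ci0 (I1 - 3)^i for an isotropic,
#' incompressible material (orders up to 6). An optional yield stress acts as
#' a perfect-plasticity cap on the uniaxial stress curve.
#'
#' @param C MPa, numeric vector of coefficients C10, C20, ... (length 1-6,
#'   missing orders zero).
#' @param yield_stress MPa, optional stress cap (NA = none).
#' @param label character tag.
#' @return object of class `rp_coeffs`.
#' @export
rp_coeffs <- function(C, yield_stress = NA_real_, label = "") {
  C <- as.numeric(C)
  if (length(C) < 1L || length(C) > 6L)
    stop("between 1 and 6 coefficients (C10..C60) required")
  if (!is.finite(C[1L])) stop("C10 must be present and finite")
  if (!is.na(yield_stress) && yield_stress <= 0)
    stop("yield_stress must be > 0 when present")
  structure(list(C = c(C, rep(0, 6L - length(C))),
                 yield_stress = yield_stress, label = label),
            class = "rp_coeffs")
}

#' @export
print.rp_coeffs <- function(x, ...) {
  cat("Reduced-polynomial material", if (nzchar(x$label)) sQuote(x$label), "\n")
  cat("  C10..C60 [MPa]:", format(x$C, digits = 4), "\n")
  if (!is.na(x$yield_stress))
    cat("  yield cap [MPa]:", x$yield_stress, "\n")
  invisible(x)
}

#' Material table for stenting simulations
#'
#' The full constitutive table used by the platform: bench silicone
#' (Neo-Hookean), normal arterial wall (sixth-order reduced polynomial), five
#' plaque classes (very soft to very stiff, mapped to integer plaque scores
#' -2..+2 with perfect-plasticity yield caps), the stent alloys (MP35N with
#' isotropic hardening, Pt-Ir core with perfect plasticity, Pt-Cr), and the
#' balloon compliance-class moduli (300/900/1500 MPa).
#'
#' The table ships as a versioned JSON resource under
#' `inst/extdata/material_table.json`; this constructor reads and validates it.
#'
#' @param path optional path to an alternative JSON table.
#' @return object of class `material_table` with elements `soft` (named list of
#'   `rp_coeffs`), `plaque_classes` (character, score -2..+2 order), `alloys`
#'   (named list of `alloy_model`), `balloon_moduli` (named numeric, MPa) and
#'   `version`.
#' @export
material_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "material_table.json", package = "stentsim",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  soft <- lapply(names(raw$soft), function(nm) {
    s <- raw$soft[[nm]]
    rp_coeffs(unlist(s$C), yield_stress = if (is.null(s$yield)) NA_real_ else s$yield,
              label = nm)
  })
  names(soft) <- names(raw$soft)
  classes <- raw$plaque_classes
  stopifnot(length(classes) == 5L, all(classes %in% names(soft)))
  alloys <- lapply(names(raw$alloys), function(nm) {
    a <- raw$alloys[[nm]]
    alloy_model(nm, elastic_modulus = a$E_GPa, yield_strength = a$yield_MPa,
                tensile_strength = if (is.null(a$tensile_MPa)) NA_real_ else a$tensile_MPa,
                elongation = if (is.null(a$elongation_pct)) NA_real_ else a$elongation_pct,
                density = a$density_g_cm3, hardening = a$hardening)
  })
  names(alloys) <- names(raw$alloys)
  structure(list(soft = soft, plaque_classes = classes, alloys = alloys,
                 balloon_moduli = unlist(raw$balloon_moduli_MPa),
                 silicone_density = raw$silicone_density_g_cm3,
                 version = raw$version),
            class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat("Material table v", x$version, ": ", length(x$soft), " soft materials, ",
      length(x$alloys), " alloys\n", sep = "")
  invisible(x)
}

#' Stent alloy elastoplastic model
#'
#' Bilinear Von Mises plasticity: linear elastic up to the 0.2% proof stress,
#' then either linear isotropic hardening to (elongation, tensile strength) or
#' a flat stress plateau (perfect plasticity, used for the Pt-Ir wire core).
#'
#' @param name alloy name.
#' @param elastic_modulus GPa.
#' @param yield_strength MPa (0.2% proof stress).
#' @param tensile_strength MPa (NA for perfect plasticity).
#' @param elongation percent at tensile strength (NA for perfect plasticity).
#' @param density g/cm^3.
#' @param hardening "isotropic" or "perfect".
#' @return object of class `alloy_model`.
#' @export
alloy_model <- function(name, elastic_modulus, yield_strength,
                        tensile_strength = NA_real_, elongation = NA_real_,
                        density = NA_real_,
                        hardening = c("isotropic", "perfect")) {
  hardening <- match.arg(hardening)
  stopifnot(elastic_modulus > 0, yield_strength > 0)
  if (hardening == "isotropic" &&
      (is.na(tensile_strength) || is.na(elongation)))
    stop("isotropic hardening requires tensile_strength and elongation")
  structure(list(name = name, elastic_modulus = elastic_modulus,
                 yield_strength = yield_strength,
                 tensile_strength = tensile_strength, elongation = elongation,
                 density = density, hardening = hardening),
            class = "alloy_model")
}

## First invariant of the left Cauchy-Green tensor under incompressible
## uniaxial stretch: I1 = lambda^2 + 2/lambda.
uniaxial_I1 <- function(stretch) stretch^2 + 2 / stretch

#' Uniaxial Cauchy stress of a reduced-polynomial material
#'
#' For incompressible uniaxial loading at stretch lambda,
#' sigma = 2 (lambda^2 - 1/lambda) * sum_i i * Ci0 * (I1 - 3)^(i-1) with
#' I1 = lambda^2 + 2/lambda. When the coefficient set carries a yield stress
#' the magnitude of the returned stress is capped there (perfect-plasticity
#' cap; see the methods vignette).
#'
#' @param coeffs an [rp_coeffs] object.
#' @param stretch dimensionless stretch lambda > 0 (vectorized).
#' @return Cauchy stress in MPa.
#' @examples
#' sil <- rp_coeffs(0.154, label = "silicone")
#' uniaxial_stress(sil, 1.1)   # ~0.0927 MPa
#' @export
uniaxial_stress <- function(coeffs, stretch) {
  stopifnot(inherits(coeffs, "rp_coeffs"))
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("stretch must be finite and > 0")
  x <- uniaxial_I1(stretch) - 3
  dWdI1 <- rep(0, length(stretch))
  for (i in 1:6) dWdI1 <- dWdI1 + i * coeffs$C[i] * x^(i - 1)
  sig <- 2 * (stretch^2 - 1 / stretch) * dWdI1
  if (!is.na(coeffs$yield_stress)) {
    y <- coeffs$yield_stress
    sig <- pmin(pmax(sig, -y), y)
  }
  sig
}

#' Strain-energy density of a reduced-polynomial material (uniaxial state)
#'
#' W(lambda) = sum_i Ci0 (I1 - 3)^i. Used as the independent differentiation
#' oracle for [uniaxial_stress] (sigma = lambda dW/dlambda for incompressible
#' uniaxial loading). The yield cap is ignored here.
#'
#' @inheritParams uniaxial_stress
#' @return energy density in MPa (= MJ/m^3).
#' @export
strain_energy <- function(coeffs, stretch) {
  stopifnot(inherits(coeffs, "rp_coeffs"))
  x <- uniaxial_I1(stretch) - 3
  W <- rep(0, length(stretch))
  for (i in 1:6) W <- W + coeffs$C[i] * x^i
  W
}

#' Neo-Hookean uniaxial Cauchy stress
#'
#' Equivalent to [uniaxial_stress] with only C10 set; used for the bench
#' silicone wall (C10 = 0.154 MPa from compression testing).
#'
#' @param C10 MPa.
#' @param stretch dimensionless.
#' @return Cauchy stress in MPa.
#' @export
neo_hookean_stress <- function(C10, stretch) {
  uniaxial_stress(rp_coeffs(C10), stretch)
}

#' Fit a Neo-Hookean C10 to uniaxial stress-stretch samples
#'
#' Least squares on sigma = 2 C10 (lambda^2 - 1/lambda); closed form.
#'
#' @param stretch vector of stretches lambda.
#' @param stress vector of Cauchy stresses, MPa.
#' @return fitted C10, MPa.
#' @export
fit_neo_hookean <- function(stretch, stress) {
  stopifnot(length(stretch) == length(stress))
  if (length(stretch) < 3L) stop("at least 3 samples required")
  g <- 2 * (stretch^2 - 1 / stretch)
  if (sum(g^2) < .Machine$double.eps)
    stop("degenerate input: all samples at the reference state")
  sum(g * stress) / sum(g^2)
}

#' Plaque score from tissue composition
#'
#' Maps per-zone aggregate area fractions of lipid, fibrous and calcified
#' tissue to a quarter-step score in [-2, +2]: +2 is calcium only (very
#' stiff), -2 lipid only (very soft). The raw score is
#' 2 (f_Ca - f_lipid) / (f_Ca + f_fibrous + f_lipid), rounded to the nearest
#' quarter with ties broken toward 0.
#'
#' @param lipid,fibrous,calcified non-negative area fractions (any common
#'   scale; they are normalized internally). Vectorized.
#' @return quarter-step score(s) in [-2, 2].
#' @examples
#' score_composition(lipid = 0, fibrous = 0, calcified = 1)  # +2
#' @export
score_composition <- function(lipid, fibrous, calcified) {
  if (any(c(lipid, fibrous, calcified) < 0)) stop("fractions must be >= 0")
  tot <- lipid + fibrous + calcified
  if (any(tot <= 0)) stop("all-zero composition")
  raw <- 2 * (calcified - lipid) / tot
  round_quarter_to_zero(raw)
}

## Round to the nearest 0.25 step; exact half-step ties go toward zero.
round_quarter_to_zero <- function(x) {
  q <- 4 * x
  aq <- abs(q)
  tie <- abs(aq %% 1 - 0.5) < 1e-9
  out <- ifelse(tie, floor(aq + 1e-9), round(aq))
  sign(q) * out / 4
}

## Map an integer score -2..+2 to its plaque class name.
score_class <- function(score, table) {
  stopifnot(score %in% -2:2)
  table$plaque_classes[score + 3L]
}

#' Stress at a given stretch for a (possibly fractional) plaque score
#'
#' Integer scores evaluate the corresponding plaque-class law exactly;
#' fractional quarter scores linearly interpolate the stress between the two
#' adjacent class laws at each stretch (caps included), so the family is
#' continuous in score.
#'
#' @param score quarter-step plaque score in [-2, 2] (scalar).
#' @param stretch stretch lambda (vectorized).
#' @param table a [material_table].
#' @return Cauchy stress, MPa.
#' @export
stress_for_score <- function(score, stretch, table = material_table()) {
  if (!is.finite(score) || score < -2 || score > 2)
    stop("score outside [-2, +2]")
  if (abs(score * 4 - round(score * 4)) > 1e-9)
    stop("score must be a quarter-step value")
  lo <- floor(score); hi <- ceiling(score)
  s_lo <- uniaxial_stress(table$soft[[score_class(lo, table)]], stretch)
  if (hi == lo) return(s_lo)
  s_hi <- uniaxial_stress(table$soft[[score_class(hi, table)]], stretch)
  w <- score - lo
  (1 - w) * s_lo + w * s_hi
}

#' Sampled stress-strain curve for a plaque score
#'
#' @inheritParams stress_for_score
#' @param stretch_max maximum stretch sampled (default 1.3).
#' @param n number of samples.
#' @return data.frame with columns `stretch`, `strain`, `stress_MPa`.
#' @export
curve_for_score <- function(score, table = material_table(),
                            stretch_max = 1.3, n = 121L) {
  lam <- seq(1, stretch_max, length.out = n)
  data.frame(stretch = lam, strain = lam - 1,
             stress_MPa = stress_for_score(score, lam, table))
}

#' Uniaxial stress of a stent alloy (bilinear elastoplasticity)
#'
#' Elastic slope E up to the yield strain; beyond it, linear hardening toward
#' (elongation, tensile strength) for isotropic-hardening alloys or a flat
#' plateau for perfect plasticity. Negative strains use the odd extension
#' (sigma(-e) = -sigma(e)), which is what the ring surrogate needs for
#' elastic unloading/compression.
#'
#' @param alloy an [alloy_model].
#' @param strain engineering strain (vectorized; may be negative).
#' @return stress, MPa.
#' @export
alloy_stress <- function(alloy, strain) {
  stopifnot(inherits(alloy, "alloy_model"))
  E <- alloy$elastic_modulus * 1000            # GPa -> MPa
  ey <- alloy$yield_strength / E
  ae <- abs(strain)
  if (alloy$hardening == "perfect") {
    s <- ifelse(ae <= ey, E * ae, alloy$yield_strength)
  } else {
    emax <- alloy$elongation / 100
    H <- (alloy$tensile_strength - alloy$yield_strength) / (emax - ey)
    s <- ifelse(ae <= ey, E * ae,
                pmin(alloy$yield_strength + H * (ae - ey),
                     alloy$tensile_strength))
  }
  sign(strain) * s
}

#' Balloon elastic modulus by compliance class
#'
#' @param class one of "compliant", "semi_compliant", "non_compliant".
#' @param table a [material_table].
#' @return elastic modulus, MPa (300, 900 or 1500).
#' @export
balloon_modulus <- function(class, table = material_table()) {
  class <- match.arg(class, c("compliant", "semi_compliant", "non_compliant"))
  unname(table$balloon_moduli[[class]])
}

#' Export a material curve to CSV
#'
#' @param curve data.frame from [curve_for_score].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_material_curve <- function(curve, path) {
  utils::write.csv(curve[, c("strain", "stress_MPa")], path, row.names = FALSE)
  invisible(path)
}
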