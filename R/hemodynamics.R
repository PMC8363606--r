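#' @title Reduced-order hemodynamics
#' @description A 1D surrogate for transient 3D CFD of the stented
#'   bifurcation: Carreau non-Newtonian blood viscosity, a diameter-scaled
#'   pulsatile coronary inlet waveform, the Huo-Kassab diameter-flow split
#'   between daughter branches, per-slice Poiseuille wall shear stress and
#'   its time average (TAWSS) along each branch.
#' @name hemodynamics
NULL

#' Flow conditions for the hemodynamic surrogate
#'
#' @param waveform data.frame with `t_s` and `q_ml_s` columns sampled over
#'   one cardiac cycle, or NULL for the packaged generic coronary waveform.
#' @param mean_flow_ml_s mean inlet flow at the 3.0 mm reference diameter
#'   (default 0.833 mL/s = 50 mL/min, a typical proximal coronary flow).
#' @param period_s cardiac period.
#' @param rho_kg_m3 blood density (1060).
#' @param mu_inf,mu0 Pa s, infinite- and zero-shear Carreau viscosities
#'   (0.0035, 0.25).
#' @param lambda_s Carreau time constant (25 s).
#' @param n_index Carreau power-law index (0.25).
#' @param cycles cycles simulated; the last is used (transient washout is a
#'   no-op in the 1D surrogate, retained as metadata).
#' @param inlet_exponent exponent of the diameter scaling of inlet flow
#'   (7/3, shared with the Huo-Kassab law).
#' @return list of class `flow_conditions`.
#' @export
flow_conditions <- function(waveform = NULL, mean_flow_ml_s = 50 / 60,
                            period_s = 0.8, rho_kg_m3 = 1060,
                            mu_inf = 0.0035, mu0 = 0.25, lambda_s = 25,
                            n_index = 0.25, cycles = 3L,
                            inlet_exponent = 7 / 3) {
  stopifnot(mu0 > mu_inf, mu_inf > 0, lambda_s > 0,
            n_index > 0, n_index < 1)
  if (is.null(waveform))
    waveform <- coronary_waveform(period_s, mean_flow_ml_s)
  stopifnot(all(c("t_s", "q_ml_s") %in% names(waveform)))
  structure(list(waveform = waveform, mean_flow_ml_s = mean_flow_ml_s,
                 period_s = period_s, rho_kg_m3 = rho_kg_m3,
                 carreau = list(mu_inf = mu_inf, mu0 = mu0,
                                lambda = lambda_s, n = n_index),
                 cycles = as.integer(cycles),
                 inlet_exponent = inlet_exponent,
                 reference_diameter_mm = 3.0,
                 metadata = list(extensions_diameters = 10,
                                 note = "recorded-not-simulated")),
            class = "flow_conditions")
}

## Generic diastolic-dominant coronary waveform: small systolic hump, large
## diastolic one; strictly positive; normalized to the requested mean.
coronary_waveform <- function(period_s = 0.8, mean_flow_ml_s = 50 / 60,
                              n = 64L) {
  u <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  shape <- 0.55 + 0.35 * exp(-((u - 0.15) / 0.10)^2) +
    1.1 * exp(-((u - 0.62) / 0.16)^2)
  shape <- shape / mean(shape)
  data.frame(t_s = u * period_s, q_ml_s = mean_flow_ml_s * shape)
}

#' Carreau apparent viscosity of blood
#'
#' mu(gdot) = mu_inf + (mu0 - mu_inf) [1 + (lambda gdot)^2]^((n-1)/2).
#' Monotone nonincreasing in shear rate for n < 1, with limits mu0 at zero
#' shear and mu_inf at infinite shear.
#'
#' @param shear_rate 1/s, >= 0 (vectorized).
#' @param conditions a [flow_conditions] (only the Carreau block is used).
#' @return apparent viscosity, Pa s.
#' @examples
#' carreau_viscosity(1e-9)  # zero-shear plateau, 0.25 Pa s
#' carreau_viscosity(1e9)   # infinite-shear plateau, 0.0035 Pa s
#' @export
carreau_viscosity <- function(shear_rate, conditions = flow_conditions()) {
  if (any(shear_rate < 0)) stop("shear rate must be >= 0")
  cc <- conditions$carreau
  cc$mu_inf + (cc$mu0 - cc$mu_inf) *
    (1 + (cc$lambda * shear_rate)^2)^((cc$n - 1) / 2)
}

#' Scale the inlet waveform to a vessel's inlet diameter
#'
#' Mean flow scales as (D / D_ref)^(7/3) relative to the 3.0 mm reference
#' (the same exponent as the Huo-Kassab law, kept configurable); the
#' waveform shape and period are preserved.
#'
#' @param conditions a [flow_conditions].
#' @param inlet_diameter_mm mm.
#' @return data.frame waveform (`t_s`, `q_ml_s`).
#' @export
scale_inlet_flow <- function(conditions, inlet_diameter_mm) {
  if (inlet_diameter_mm <= 0) stop("diameter must be > 0")
  w <- conditions$waveform
  w$q_ml_s <- w$q_ml_s *
    (inlet_diameter_mm / conditions$reference_diameter_mm)^
      conditions$inlet_exponent
  w
}

#' Huo-Kassab flow split between daughter branches
#'
#' Q_mv / Q_sb = (d_mv / d_sb)^(7/3); returns the flow fractions of the two
#' daughters (summing to 1).
#'
#' @param d_mv_distal,d_sb daughter diameters, mm.
#' @param exponent scaling exponent (default 7/3).
#' @return named numeric c(mv = , sb = ).
#' @export
hk_split <- function(d_mv_distal, d_sb, exponent = 7 / 3) {
  stopifnot(d_mv_distal > 0, d_sb > 0)
  ratio <- (d_mv_distal / d_sb)^exponent
  c(mv = ratio / (1 + ratio), sb = 1 / (1 + ratio))
}

#' Poiseuille wall shear stress with Carreau viscosity
#'
#' Fixed point of tau = 4 mu(gdot_w) Q / (pi r^3) with the wall shear rate
#' gdot_w = 4 Q / (pi r^3); converged to a relative tolerance of 1e-8
#' (immediate for the Poiseuille wall shear rate, which does not depend on
#' viscosity; the iteration guards config-swapped rheologies).
#'
#' @param q_ml_s flow, mL/s (>= 0).
#' @param radius_mm lumen radius, mm.
#' @param conditions a [flow_conditions].
#' @return wall shear stress, Pa.
#' @export
slice_wss <- function(q_ml_s, radius_mm, conditions = flow_conditions()) {
  if (any(q_ml_s < 0)) stop("flow must be >= 0")
  if (any(radius_mm <= 0)) stop("radius must be > 0")
  q_mm3 <- q_ml_s * 1000                       # mL/s -> mm^3/s
  gw <- 4 * q_mm3 / (pi * radius_mm^3)         # 1/s
  tau <- 4 * carreau_viscosity(gw, conditions) * q_mm3 / (pi * radius_mm^3)
  for (i in 1:50) {
    tau_new <- 4 * carreau_viscosity(gw, conditions) * q_mm3 /
      (pi * radius_mm^3)
    if (all(abs(tau_new - tau) <= 1e-8 * pmax(abs(tau), 1e-300))) {
      tau <- tau_new
      break
    }
    tau <- tau_new
  }
  tau                                          # Pa.s * 1/s = Pa
}

#' Time-averaged wall shear stress along both branches
#'
#' Branch flows follow the Huo-Kassab split of the diameter-scaled inlet
#' waveform; per slice, TAWSS is the cycle mean of the Poiseuille-Carreau
#' wall shear stress. Flow is conserved exactly: Q_in = Q_mv + Q_sb at every
#' time sample.
#'
#' @param profile_mv,profile_sb data.frames with `arclength_mm` and
#'   `diameter_mm` (e.g. from [slice_profile] or [mld_profile]).
#' @param conditions a [flow_conditions].
#' @param carina_arclength_mm carina location on the MV profile (flow
#'   changes from inlet to distal-MV flow there).
#' @return object of class `wss_profile`: data.frame with branch,
#'   arclength_mm, tawss_pa, plus the branch flow fractions.
#' @export
tawss_profile <- function(profile_mv, profile_sb,
                          conditions = flow_conditions(),
                          carina_arclength_mm) {
  d_in <- profile_mv$diameter_mm[which.min(profile_mv$arclength_mm)]
  d_mv_dist <- profile_mv$diameter_mm[which.max(profile_mv$arclength_mm)]
  d_sb <- profile_sb$diameter_mm[which.max(profile_sb$arclength_mm)]
  split <- hk_split(d_mv_dist, d_sb)
  w <- scale_inlet_flow(conditions, d_in)
  taw <- function(diam, frac) {
    vapply(diam, function(d) {
      if (is.na(d)) return(NA_real_)
      mean(slice_wss(frac * w$q_ml_s, d / 2, conditions))
    }, numeric(1L))
  }
  prox <- profile_mv$arclength_mm <= carina_arclength_mm
  tawss_mv <- numeric(nrow(profile_mv))
  tawss_mv[prox] <- taw(profile_mv$diameter_mm[prox], 1)
  tawss_mv[!prox] <- taw(profile_mv$diameter_mm[!prox], split[["mv"]])
  tawss_sb <- taw(profile_sb$diameter_mm, split[["sb"]])
  structure(list(
    profile = rbind(
      data.frame(branch = "MV", arclength_mm = profile_mv$arclength_mm,
                 tawss_pa = tawss_mv),
      data.frame(branch = "SB", arclength_mm = profile_sb$arclength_mm,
                 tawss_pa = tawss_sb)),
    split = split, conditions = conditions),
    class = "wss_profile")
}

#' @export
print.wss_profile <- function(x, ...) {
  cat("TAWSS profile:", nrow(x$profile), "slices; flow split MV",
      round(x$split[["mv"]], 3), "/ SB", round(x$split[["sb"]], 3), "\n")
  invisible(x)
}

#' Export a TAWSS profile to CSV
#'
#' @param wss a `wss_profile`.
#' @param path output path.
#' @param label optional pre/post label column.
#' @return `path`, invisibly.
#' @export
write_wss_csv <- function(wss, path, label = NA_character_) {
  df <- wss$profile
  df$label <- label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
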