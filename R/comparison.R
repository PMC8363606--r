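#' @title Comparison metrics and Bland-Altman agreement
#' @description The validation harness: mean-lumen-diameter (MLD) and
#'   mean-stent-diameter (MSD) profiles along a branch, carina-referenced
#'   co-registration of simulated versus reference profiles, Bland-Altman
#'   bias and 95% limits of agreement, and pooled report tables.
#' @name comparison
NULL

#' Diameter profile container
#'
#' @param arclength_mm strictly increasing sample positions.
#' @param diameter_mm diameters (> 0; NA = absent slice).
#' @param carina_arclength_mm carina position used for co-registration.
#' @param label free-text label.
#' @return object of class `diameter_profile`.
#' @export
diameter_profile <- function(arclength_mm, diameter_mm, carina_arclength_mm,
                             label = "") {
  ok <- !is.na(diameter_mm)
  if (any(diff(arclength_mm) <= 0))
    stop("arclength samples must be strictly increasing")
  if (any(diameter_mm[ok] <= 0)) stop("diameters must be > 0")
  structure(list(arclength_mm = arclength_mm, diameter_mm = diameter_mm,
                 carina_arclength_mm = carina_arclength_mm, label = label),
            class = "diameter_profile")
}

#' Lumen diameter (MLD) profile
#'
#' Per-slice area-equivalent diameter 2 sqrt(A/pi) along a branch. Methods
#' exist for reconstructed geometries (ring areas), deployment states (slice
#' radii) and synthetic anatomies (analytic profile). A chord-averaged
#' alternative (mean diameter over diametral rays) is available for ring
#' geometries via `method = "chord"`.
#'
#' @param x geometry/state object.
#' @param ... passed to methods (`branch`, `spacing`, `method`).
#' @return a [diameter_profile].
#' @export
mld_profile <- function(x, ...) UseMethod("mld_profile")

#' @rdname mld_profile
#' @param branch "MV" or "SB".
#' @param spacing sample spacing, mm.
#' @param method "area" (area-equivalent, default) or "chord".
#' @export
mld_profile.bifurcation_geometry <- function(x, branch = "MV", spacing = 0.5,
                                             method = c("area", "chord"),
                                             ...) {
  method <- match.arg(method)
  br <- if (toupper(branch) == "MV") x$mv else x$sb
  mld_profile_rings(br, branch, spacing, method,
                    if (toupper(branch) == "MV")
                      x$mv$centerline$carina_arclength else 0)
}

#' @rdname mld_profile
#' @export
mld_profile.lofted_branch <- function(x, spacing = 0.5,
                                      method = c("area", "chord"), ...) {
  method <- match.arg(method)
  car <- if (toupper(x$branch) == "MV") x$centerline$carina_arclength else 0
  mld_profile_rings(x, x$branch, spacing, method, car)
}

mld_profile_rings <- function(br, branch, spacing, method, carina) {
  if (method == "area") {
    areas <- vapply(br$rings_lumen, ring_area, numeric(1L))
    d <- 2 * sqrt(areas / pi)
  } else {
    d <- vapply(br$rings_lumen, function(ring) {
      n <- nrow(ring)
      half <- seq_len(n %/% 2)
      mean(sqrt(rowSums((ring[half, , drop = FALSE] -
                         ring[half + n %/% 2, , drop = FALSE])^2)))
    }, numeric(1L))
  }
  s_out <- seq(min(br$s), max(br$s), by = spacing)
  diameter_profile(s_out, stats::approx(br$s, d, xout = s_out)$y,
                   carina, label = paste0("recon_", branch))
}

#' @rdname mld_profile
#' @export
mld_profile.deployment_state <- function(x, branch = "MV", spacing = NULL,
                                         ...) {
  sl <- anat_branch(x, branch)$slices
  car <- if (toupper(branch) == "MV") x$carina_arclength else 0
  if (!is.null(spacing)) {
    s_out <- seq(min(sl$arclength), max(sl$arclength), by = spacing)
    d <- stats::approx(sl$arclength, 2 * sl$r, xout = s_out)$y
    diameter_profile(s_out, d, car, label = paste0("sim_", branch))
  } else {
    diameter_profile(sl$arclength, 2 * sl$r, car,
                     label = paste0("sim_", branch))
  }
}

#' @rdname mld_profile
#' @export
mld_profile.bifurcation_anatomy <- function(x, branch = "MV", spacing = 0.25,
                                            ...) {
  b <- anat_branch(x, branch)
  s_out <- seq(min(b$s), max(b$s), by = spacing)
  car <- if (toupper(branch) == "MV") x$carina$arclength else 0
  diameter_profile(s_out, branch_diameter(x, branch, s_out), car,
                   label = paste0("anatomy_", branch))
}

#' Stent diameter (MSD) profile
#'
#' Per-slice area-equivalent diameter of the stent ring polygon through the
#' strut centroids. For a deployment state, the ring radius of the layer(s)
#' on each stented slice; for a reconstructed/deployed stent geometry, the
#' polygon of node positions binned per axial slice. Empty slices are
#' absent (NA), not zero.
#'
#' @param x a `deployment_state` or `stent_geometry`.
#' @param ... passed to methods.
#' @return a [diameter_profile].
#' @export
msd_profile <- function(x, ...) UseMethod("msd_profile")

#' @rdname msd_profile
#' @param branch "MV" or "SB".
#' @param stent_id restrict to one stent (default: innermost layer).
#' @export
msd_profile.deployment_state <- function(x, branch = "MV", stent_id = NULL,
                                         ...) {
  br <- anat_branch(x, branch)
  sl <- br$slices
  d <- rep(NA_real_, nrow(sl))
  for (i in seq_len(nrow(sl))) {
    rr <- numeric()
    for (ly in br$layers[[i]]) {
      if (!is.null(stent_id) && ly$stent_id != stent_id) next
      rl <- min(sl$r[i], ly$r_set) - ly$thickness / 2
      rr <- c(rr, rl)
    }
    if (length(rr)) d[i] <- 2 * max(rr)
  }
  car <- if (toupper(branch) == "MV") x$carina_arclength else 0
  diameter_profile(sl$arclength, d, car, label = paste0("msd_", branch))
}

#' @rdname msd_profile
#' @param slice_spacing axial bin width, mm.
#' @export
msd_profile.stent_geometry <- function(x, slice_spacing = 0.5, ...) {
  stopifnot(!is.null(x$arclength))
  s <- x$arclength
  bins <- seq(floor(min(s) / slice_spacing) * slice_spacing,
              max(s) + slice_spacing, by = slice_spacing)
  mid <- bins[-length(bins)] + slice_spacing / 2
  d <- rep(NA_real_, length(mid))
  for (i in seq_along(mid)) {
    sel <- s >= bins[i] & s < bins[i + 1L]
    if (sum(sel) >= 3L) {
      pts <- x$nodes[sel, , drop = FALSE]
      ctr <- colMeans(pts)
      sv <- svd(sweep(pts, 2L, ctr))
      uv <- sweep(pts, 2L, ctr) %*% sv$v[, 1:2]
      th <- atan2(uv[, 2L], uv[, 1L])
      ord <- order(th)
      ## upsample the strut-centroid ring with a periodic spline so the
      ## sparse crown polygon does not underestimate the enclosed area
      rr <- sqrt(rowSums(uv^2))[ord]
      tt <- th[ord]
      f <- stats::splinefun(c(tt, tt[1L] + 2 * pi), c(rr, rr[1L]),
                            method = "periodic")
      td <- seq(tt[1L], tt[1L] + 2 * pi, length.out = 65L)[-65L]
      rd <- f(td)
      d[i] <- 2 * sqrt(polygon_area(rd * cos(td), rd * sin(td)) / pi)
    }
  }
  keep <- !is.na(d)
  diameter_profile(mid[keep], d[keep], carina_arclength_mm = 0,
                   label = "msd_recon")
}

#' Co-register two diameter profiles at the carina
#'
#' Both profiles are shifted so their carina arclengths align; pairs are
#' formed at the simulated profile's samples over the common range by linear
#' interpolation of the reference.
#'
#' @param profile_sim,profile_ref [diameter_profile] objects.
#' @return data.frame: `arclength_mm` (carina-relative), `sim_mm`, `ref_mm`,
#'   `diff_mm` (sim - ref).
#' @export
coregister <- function(profile_sim, profile_ref) {
  stopifnot(inherits(profile_sim, "diameter_profile"),
            inherits(profile_ref, "diameter_profile"))
  s_sim <- profile_sim$arclength_mm - profile_sim$carina_arclength_mm
  s_ref <- profile_ref$arclength_mm - profile_ref$carina_arclength_mm
  lo <- max(min(s_sim), min(s_ref))
  hi <- min(max(s_sim), max(s_ref))
  if (hi <= lo) stop("profiles do not overlap after co-registration")
  sel <- s_sim >= lo & s_sim <= hi & !is.na(profile_sim$diameter_mm)
  ref <- stats::approx(s_ref, profile_ref$diameter_mm,
                       xout = s_sim[sel])$y
  ok <- !is.na(ref)
  data.frame(arclength_mm = s_sim[sel][ok],
             sim_mm = profile_sim$diameter_mm[sel][ok],
             ref_mm = ref[ok],
             diff_mm = profile_sim$diameter_mm[sel][ok] - ref[ok])
}

#' Bland-Altman agreement statistics
#'
#' Bias = mean(sim - ref); sample (n-1) standard deviation; 95% limits of
#' agreement = bias +/- 1.96 sd. The bias is the exact midpoint of the
#' limits by construction.
#'
#' @param pairs data.frame from [coregister] (or any with `diff_mm`), or a
#'   numeric vector of differences.
#' @return object of class `bland_altman`: bias, sd, loa_low, loa_high, n
#'   (all mm).
#' @export
bland_altman <- function(pairs) {
  d <- if (is.data.frame(pairs)) pairs$diff_mm else as.numeric(pairs)
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("at least 2 paired differences required")
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f mm (95%% LoA %.3f to %.3f), n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Bias implied by printed limits of agreement
#'
#' The Bland-Altman convention bias = (loa_low + loa_high) / 2, used to
#' check printed tables for internal consistency.
#'
#' @param loa_low,loa_high printed 95% limits, mm.
#' @return midpoint, mm.
#' @export
ba_bias_from_limits <- function(loa_low, loa_high) (loa_low + loa_high) / 2

#' Agreement report table over cases and branches
#'
#' One row per case/branch plus an overall row computed by pooling all
#' paired differences (not by averaging the per-case biases).
#'
#' @param pair_sets named list of paired-difference data.frames (from
#'   [coregister]).
#' @return data.frame: case, bias_mm, loa_low_mm, loa_high_mm, n; class
#'   `ba_report`.
#' @export
report_tables <- function(pair_sets) {
  if (length(pair_sets) == 0L) stop("empty input")
  rows <- lapply(names(pair_sets), function(nm) {
    ba <- bland_altman(pair_sets[[nm]])
    data.frame(case = nm, bias_mm = ba$bias, loa_low_mm = ba$loa_low,
               loa_high_mm = ba$loa_high, n = ba$n)
  })
  pooled <- bland_altman(unlist(lapply(pair_sets, function(p) p$diff_mm)))
  out <- rbind(do.call(rbind, rows),
               data.frame(case = "Overall", bias_mm = pooled$bias,
                          loa_low_mm = pooled$loa_low,
                          loa_high_mm = pooled$loa_high, n = pooled$n))
  class(out) <- c("ba_report", "data.frame")
  out
}

#' Format an agreement report as markdown
#'
#' Mirrors the bias / 95% limits-of-agreement column layout of the
#' validation tables.
#'
#' @param report a `ba_report`.
#' @return character vector of markdown lines.
#' @export
format_ba_markdown <- function(report) {
  c("| Case | Bias (mm) | 95% limits of agreement (mm) | n |",
    "|---|---|---|---|",
    sprintf("| %s | %.2f | %.2f to %.2f | %d |", report$case,
            report$bias_mm, report$loa_low_mm, report$loa_high_mm,
            report$n))
}
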