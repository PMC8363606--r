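#' @title Synthetic bifurcation anatomy and OCT-like pullbacks
#' @description Generates every input the pipeline needs without any imaging
#'   data: tapered coronary bifurcations with cosine-shaped stenoses and a
#'   heterogeneous plaque composition map, OCT-like pullbacks (per-frame lumen
#'   and outer contours with optional missing arcs and composition arcs),
#'   parallel biplane projections, bench-silicone variants, and procedure
#'   tables for the standard bifurcation stenting techniques.
#'
#'   Convention: right-handed coordinates in mm; centerline arclength measured
#'   from the proximal main-vessel (MV) inlet; the carina sits at a stored MV
#'   arclength; side-branch (SB) arclength is measured from the carina.
#' @name synthetic-anatomy
NULL

## Run expr with a private RNG stream; global .Random.seed untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters of a synthetic coronary bifurcation
#'
#' @param proximal_mv_diameter,distal_mv_diameter mm; the MV lumen tapers
#'   linearly between them over `mv_length`.
#' @param sb_diameter mm, SB lumen diameter (untapered).
#' @param bifurcation_angle degrees between MV and SB directions at the carina.
#' @param mv_length,sb_length mm.
#' @param carina_arclength mm from the MV inlet.
#' @param taper_rate mm/mm; defaults to the rate implied by the two MV
#'   diameters.
#' @param stenoses data.frame with columns `branch` ("MV"/"SB"),
#'   `center_mm` (arclength of the stenosis center), `severity` (diameter
#'   stenosis fraction in [0,1)), `length_mm`. Stenoses are cosine-tapered in
#'   diameter. A stenosis overlapping the carina within one local reference
#'   diameter is rejected.
#' @param wall_thickness mm; constant, or a function of arclength.
#' @param composition_map function(s, branch) returning the c(lipid, fibrous,
#'   calcified) area fractions (must sum to 1); the default is a fibrous
#'   background with a lipid-rich shoulder and a calcific core at each
#'   stenosis.
#' @param curvature_radius mm, radius of the in-plane MV arc (Inf = straight).
#' @param slice_spacing mm between stored anatomy slices.
#' @param n_angles angular samples per cross-section contour.
#' @param seed integer seed for all downstream sampling.
#' @return object of class `anatomy_params`.
#' @export
anatomy_params <- function(proximal_mv_diameter = 3.5,
                           distal_mv_diameter = 3.0,
                           sb_diameter = 2.5,
                           bifurcation_angle = 60,
                           mv_length = 30, sb_length = 15,
                           carina_arclength = 18,
                           taper_rate = NULL,
                           stenoses = NULL,
                           wall_thickness = 0.9,
                           composition_map = NULL,
                           curvature_radius = Inf,
                           slice_spacing = 0.25,
                           n_angles = 64L,
                           seed = 1L) {
  if (proximal_mv_diameter <= 0 || distal_mv_diameter <= 0 || sb_diameter <= 0)
    stop("diameters must be > 0")
  if (distal_mv_diameter > proximal_mv_diameter)
    stop("distal MV diameter must not exceed proximal")
  if (is.null(taper_rate))
    taper_rate <- (proximal_mv_diameter - distal_mv_diameter) / mv_length
  if (is.null(stenoses))
    stenoses <- data.frame(branch = character(), center_mm = numeric(),
                           severity = numeric(), length_mm = numeric())
  stopifnot(all(c("branch", "center_mm", "severity", "length_mm") %in%
                names(stenoses)))
  if (any(stenoses$severity < 0 | stenoses$severity >= 1))
    stop("diameter stenosis fraction must be in [0, 1)")
  if (carina_arclength <= 0 || carina_arclength >= mv_length)
    stop("carina must lie strictly inside the MV")
  if (is.null(composition_map))
    composition_map <- default_composition_map(stenoses)
  wt <- if (is.function(wall_thickness)) wall_thickness
        else {w <- wall_thickness; function(s, branch) rep(w, length(s))}
  structure(list(proximal_mv_diameter = proximal_mv_diameter,
                 distal_mv_diameter = distal_mv_diameter,
                 sb_diameter = sb_diameter,
                 bifurcation_angle = bifurcation_angle,
                 mv_length = mv_length, sb_length = sb_length,
                 carina_arclength = carina_arclength,
                 taper_rate = taper_rate, stenoses = stenoses,
                 wall_thickness = wt, composition_map = composition_map,
                 curvature_radius = curvature_radius,
                 slice_spacing = slice_spacing,
                 n_angles = as.integer(n_angles), seed = as.integer(seed)),
            class = "anatomy_params")
}

## Default plaque composition: fibrous background, lipid shoulder + calcific
## core around each stenosis. Arbitrary but documented (methods vignette).
default_composition_map <- function(stenoses) {
  force(stenoses)
  function(s, branch) {
    lipid <- 0.15; calc <- 0.05
    st <- stenoses[stenoses$branch == branch, , drop = FALSE]
    for (k in seq_len(nrow(st))) {
      u <- (s - st$center_mm[k]) / (st$length_mm[k] / 2)
      if (abs(u) <= 1) {
        bump <- 0.5 * (1 + cos(pi * u))
        lipid <- lipid + 0.25 * bump
        calc <- calc + 0.20 * bump * st$severity[k]
      }
    }
    f <- c(lipid = lipid, fibrous = 1 - lipid - calc, calcified = calc)
    f / sum(f)
  }
}

## Cosine-tapered diameter stenosis factor at arclengths s for one branch.
stenosis_factor <- function(s, branch, stenoses) {
  f <- rep(1, length(s))
  st <- stenoses[stenoses$branch == branch, , drop = FALSE]
  for (k in seq_len(nrow(st))) {
    u <- (s - st$center_mm[k]) / (st$length_mm[k] / 2)
    inside <- abs(u) <= 1
    f[inside] <- f[inside] *
      (1 - st$severity[k] * 0.5 * (1 + cos(pi * u[inside])))
  }
  f
}

#' Generate a synthetic bifurcation anatomy
#'
#' Builds MV and SB centerlines joined at the carina, per-slice lumen radii
#' from the analytic taper-times-stenosis diameter profile, wall thickness and
#' plaque composition samples. Surfaces are available on demand through
#' [anatomy_mesh]. Deterministic for fixed parameters and seed.
#'
#' @param params an [anatomy_params] object.
#' @return object of class `bifurcation_anatomy` with per-branch elements
#'   `s` (arclength), `centerline` (n x 3), `radius` (lumen), `wall`
#'   (thickness), `comp` (n x 3 composition fractions) plus `carina`,
#'   `angles_deg` and a parameter echo.
#' @export
generate_bifurcation <- function(params) {
  stopifnot(inherits(params, "anatomy_params"))
  p <- params
  ## reject stenoses too close to the carina
  for (k in seq_len(nrow(p$stenoses))) {
    st <- p$stenoses[k, ]
    ref_d <- if (st$branch == "MV")
      p$proximal_mv_diameter - p$taper_rate * p$carina_arclength
    else p$sb_diameter
    dist_car <- if (st$branch == "MV") abs(st$center_mm - p$carina_arclength)
                else st$center_mm
    if (dist_car - st$length_mm / 2 < ref_d)
      stop(sprintf("stenosis #%d (%s) overlaps the carina within one reference diameter (%.2f mm)",
                   k, st$branch, ref_d))
  }

  s_mv <- seq(0, p$mv_length, by = p$slice_spacing)
  if (s_mv[length(s_mv)] < p$mv_length) s_mv <- c(s_mv, p$mv_length)
  if (is.finite(p$curvature_radius)) {
    R <- p$curvature_radius
    phi <- s_mv / R
    cl_mv <- cbind(R * sin(phi), R * (1 - cos(phi)), 0)
    tan_car <- c(cos(p$carina_arclength / R), sin(p$carina_arclength / R), 0)
  } else {
    cl_mv <- cbind(s_mv, 0, 0)
    tan_car <- c(1, 0, 0)
  }
  carina_pt <- resample_polyline(cl_mv, s_mv, p$carina_arclength)

  ang <- p$bifurcation_angle * pi / 180
  ## SB direction: MV carina tangent rotated by the bifurcation angle about z
  rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3L, 3L)
  dir_sb <- as.numeric(rot %*% tan_car)
  s_sb <- seq(0, p$sb_length, by = p$slice_spacing)
  if (s_sb[length(s_sb)] < p$sb_length) s_sb <- c(s_sb, p$sb_length)
  cl_sb <- cbind(carina_pt[1L] + s_sb * dir_sb[1L],
                 carina_pt[2L] + s_sb * dir_sb[2L],
                 carina_pt[3L] + s_sb * dir_sb[3L])

  r_mv <- (p$proximal_mv_diameter - p$taper_rate * s_mv) *
    stenosis_factor(s_mv, "MV", p$stenoses) / 2
  r_sb <- p$sb_diameter * stenosis_factor(s_sb, "SB", p$stenoses) / 2
  comp_mv <- t(vapply(s_mv, function(s) p$composition_map(s, "MV"),
                      numeric(3L)))
  comp_sb <- t(vapply(s_sb, function(s) p$composition_map(s, "SB"),
                      numeric(3L)))
  colnames(comp_mv) <- colnames(comp_sb) <- c("lipid", "fibrous", "calcified")
  if (any(abs(rowSums(comp_mv) - 1) > 1e-9) ||
      any(abs(rowSums(comp_sb) - 1) > 1e-9))
    stop("composition fractions must sum to 1")

  echo <- p[setdiff(names(p), c("wall_thickness", "composition_map"))]
  structure(list(
    mv = list(s = s_mv, centerline = cl_mv, radius = r_mv,
              wall = p$wall_thickness(s_mv, "MV"), comp = comp_mv),
    sb = list(s = s_sb, centerline = cl_sb, radius = r_sb,
              wall = p$wall_thickness(s_sb, "SB"), comp = comp_sb),
    carina = list(point = as.numeric(carina_pt),
                  arclength = p$carina_arclength),
    angles_deg = seq(0, 360, length.out = p$n_angles + 1L)[-(p$n_angles + 1L)],
    material = "tissue", seed = p$seed, params = echo),
    class = "bifurcation_anatomy")
}

#' @export
print.bifurcation_anatomy <- function(x, ...) {
  cat("Synthetic bifurcation: MV", max(x$mv$s), "mm, SB", max(x$sb$s),
      "mm, carina at", x$carina$arclength, "mm,",
      nrow(x$params$stenoses), "stenosis/es,", x$material, "wall\n")
  invisible(x)
}

## Branch accessor ("MV"/"SB"), lower-case list element.
anat_branch <- function(anatomy, branch) {
  branch <- match.arg(toupper(branch), c("MV", "SB"))
  anatomy[[tolower(branch)]]
}

#' Analytic lumen diameter profile of a synthetic branch
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param branch "MV" or "SB".
#' @param s arclengths (mm); SB arclength from the carina.
#' @return diameters, mm.
#' @export
branch_diameter <- function(anatomy, branch, s) {
  b <- anat_branch(anatomy, branch)
  2 * stats::approx(b$s, b$radius, xout = s, rule = 2)$y
}

#' Plaque score along a synthetic branch
#'
#' Scores the stored composition fractions with [score_composition];
#' bench-silicone variants have no plaque and return NA.
#'
#' @inheritParams branch_diameter
#' @return quarter-step scores (NA for bench models).
#' @export
plaque_score_at <- function(anatomy, branch, s) {
  if (anatomy$material == "silicone") return(rep(NA_real_, length(s)))
  b <- anat_branch(anatomy, branch)
  comp <- resample_polyline(b$comp, b$s, s)
  comp <- matrix(comp, ncol = 3L)
  score_composition(comp[, 1L], comp[, 2L], comp[, 3L])
}

#' Watertight surface mesh of a synthetic anatomy
#'
#' Polygonizes the implicit union of the MV and SB tubes (lumen, or outer
#' wall) with marching tetrahedra; watertight by construction.
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param surface "lumen" or "wall".
#' @param h grid resolution, mm.
#' @return list with `mesh` (triangles) and `volume_mm3` (voxel-counted).
#' @export
anatomy_mesh <- function(anatomy, surface = c("lumen", "wall"), h = 0.4) {
  surface <- match.arg(surface)
  off_mv <- if (surface == "wall") anatomy$mv$wall else 0
  off_sb <- if (surface == "wall") anatomy$sb$wall else 0
  r_mv <- anatomy$mv$radius + off_mv
  r_sb <- anatomy$sb$radius + off_sb
  field <- function(pts) {
    pmin(tube_field(pts, anatomy$mv$centerline, r_mv),
         tube_field(pts, anatomy$sb$centerline, r_sb))
  }
  allpts <- rbind(anatomy$mv$centerline, anatomy$sb$centerline)
  marg <- max(r_mv, r_sb) + 2 * h
  implicit_surface(field, apply(allpts, 2L, min) - marg,
                   apply(allpts, 2L, max) + marg, h = h)
}

#' Generate an OCT-like pullback from a synthetic anatomy
#'
#' Frames are planar cross-sections perpendicular to the branch centerline,
#' ordered distal to proximal as in a catheter pullback. Outer-wall dropout
#' arcs are injected by a caller-supplied sampler; plaque composition arcs
#' partition the circumference in proportion to the local composition map
#' with a seeded random rotation per frame.
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param branch "MV" or "SB".
#' @param frame_spacing mm between frames.
#' @param dropout_sampler NULL (no dropout) or function(frame_index) returning
#'   a 2-column matrix of missing arcs (start, end) in degrees.
#' @param seed integer; defaults to the anatomy seed.
#' @return object of class `oct_pullback`: list of frames, `frame_spacing`,
#'   `branch`, `carina_frame_index`. Each frame holds `angles_deg`,
#'   `lumen_radius`, `outer_radius` (NA inside missing arcs), `missing_arcs`
#'   and `composition` (start/end/tissue/thickness), plus its true arclength
#'   as attribute `arclength` (generator metadata for round-trip oracles).
#' @export
generate_oct_pullback <- function(anatomy, branch = "MV", frame_spacing = 0.5,
                                  dropout_sampler = NULL, seed = NULL) {
  stopifnot(inherits(anatomy, "bifurcation_anatomy"))
  if (frame_spacing <= 0) stop("frame_spacing must be > 0")
  b <- anat_branch(anatomy, branch)
  L <- max(b$s)
  if (frame_spacing > L) stop("frame_spacing exceeds branch length")
  if (is.null(seed)) seed <- anatomy$seed
  nfr <- floor(L / frame_spacing) + 1L
  s_frames <- L - (seq_len(nfr) - 1L) * frame_spacing   # distal -> proximal
  carina_s <- if (toupper(branch) == "MV") anatomy$carina$arclength else 0
  carina_idx <- which.min(abs(s_frames - carina_s))
  ang <- anatomy$angles_deg
  na <- length(ang)
  frames <- with_seed(seed, lapply(seq_len(nfr), function(i) {
    s <- s_frames[i]
    r <- stats::approx(b$s, b$radius, xout = s, rule = 2)$y
    w <- stats::approx(b$s, b$wall, xout = s, rule = 2)$y
    lum <- rep(r, na)
    out <- rep(r + w, na)
    arcs <- if (is.null(dropout_sampler)) matrix(numeric(), 0L, 2L)
            else {
              a <- dropout_sampler(i)
              if (is.null(a) || length(a) == 0L) matrix(numeric(), 0L, 2L)
              else matrix(a, ncol = 2L)
            }
    for (k in seq_len(nrow(arcs)))
      out[angle_in_arc(ang, arcs[k, 1L], arcs[k, 2L])] <- NA_real_
    comp <- resample_polyline(b$comp, b$s, s)
    comp <- as.numeric(comp) / sum(comp)
    off <- stats::runif(1L, 0, 360)
    edges <- off + 360 * cumsum(c(0, comp))
    comp_df <- data.frame(start_deg = edges[1:3] %% 360,
                          end_deg = edges[2:4] %% 360,
                          tissue = c("lipid", "fibrous", "calcified"),
                          thickness_mm = w)
    comp_df <- comp_df[comp > 1e-9, , drop = FALSE]
    fr <- structure(list(angles_deg = ang, lumen_radius = lum,
                         outer_radius = out, missing_arcs = arcs,
                         composition = comp_df),
                    class = "oct_frame")
    attr(fr, "arclength") <- s
    fr
  }))
  structure(list(frames = frames, frame_spacing = frame_spacing,
                 branch = toupper(branch), carina_frame_index = carina_idx),
            class = "oct_pullback")
}

## TRUE where angle (deg) lies inside arc [start, end) mod 360.
angle_in_arc <- function(angle, start, end) {
  a <- (angle - start) %% 360
  len <- (end - start) %% 360
  if (len == 0) len <- 360
  a < len
}

#' @export
print.oct_pullback <- function(x, ...) {
  cat("OCT pullback:", length(x$frames), "frames @", x$frame_spacing,
      "mm,", x$branch, "branch, carina frame", x$carina_frame_index, "\n")
  invisible(x)
}

#' Project a synthetic anatomy onto two angiographic planes
#'
#' Parallel projection. Every view plane contains the table (x) axis; a view
#' at angle alpha has in-plane basis u = (1,0,0), w = (0, cos a, sin a) and
#' projection direction normal to the plane. Views closer than 30 degrees are
#' rejected, mirroring the two-angiographic-views limitation of biplane
#' reconstruction.
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param view_angle_a,view_angle_b view angles in degrees.
#' @return list of two views; each view holds `projection_curve` objects for
#'   the MV and SB centerlines and silhouette polylines.
#' @export
project_to_planes <- function(anatomy, view_angle_a = 0, view_angle_b = 90) {
  if (abs(view_angle_a - view_angle_b) < 30)
    stop("angiographic views must be at least 30 degrees apart")
  lapply(stats::setNames(c(view_angle_a, view_angle_b), c("view_a", "view_b")),
         function(alpha) {
           list(mv = project_curve(anatomy$mv$centerline, anatomy$mv$radius,
                                   alpha),
                sb = project_curve(anatomy$sb$centerline, anatomy$sb$radius,
                                   alpha))
         })
}

## Parallel projection of one centerline (+ radius silhouette) onto the view
## plane at angle alpha (degrees).
project_curve <- function(cl, radius, alpha) {
  a <- alpha * pi / 180
  w <- c(0, cos(a), sin(a))
  pts <- cbind(axial = cl[, 1L],
               v = cl[, 2L] * w[2L] + cl[, 3L] * w[3L])
  structure(list(points = pts, view_angle = alpha,
                 plane = list(u = c(1, 0, 0), w = w,
                              normal = c(0, -sin(a), cos(a))),
                 silhouette = list(cbind(pts[, 1L], pts[, 2L] + radius),
                                   cbind(pts[, 1L], pts[, 2L] - radius))),
            class = "projection_curve")
}

#' Bench-silicone variant of a synthetic anatomy
#'
#' Uniform wall thickness, Neo-Hookean silicone material tag, no plaque
#' (plaque queries return NA).
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param silicone_thickness mm, > 0.
#' @return a `bifurcation_anatomy` with `material = "silicone"`.
#' @export
generate_bench_variant <- function(anatomy, silicone_thickness = 1.0) {
  if (silicone_thickness <= 0) stop("thickness must be > 0")
  out <- anatomy
  out$mv$wall <- rep(silicone_thickness, length(out$mv$s))
  out$sb$wall <- rep(silicone_thickness, length(out$sb$s))
  out$mv$comp[] <- NA_real_
  out$sb$comp[] <- NA_real_
  out$material <- "silicone"
  out
}

#' Generate a procedure table for a standard bifurcation technique
#'
#' Produces the ordered step list (stenting, POT, SB strut opening, KBI,
#' pre/post-dilatation) for the named technique with the supplied devices,
#' following the procedural-step grammar of bench and clinical stenting
#' protocols.
#'
#' @param template "provisional", "TAP", "TAP_long_protrusion" or "culotte".
#' @param devices named list of device descriptions from [stent_device] /
#'   [balloon_device]. Required names depend on the template: `mv_stent`
#'   (all but culotte), `sb_stent` (TAP/culotte), `pot_balloon`, `sb_balloon`
#'   (SB strut opening), and optional `kbi_mv`/`kbi_sb`.
#' @return object of class `procedure_table`.
#' @export
generate_procedure <- function(template = c("provisional", "TAP", "culotte",
                                            "TAP_long_protrusion"),
                               devices) {
  template <- match.arg(template)
  if (missing(devices) || length(devices) == 0L)
    stop("empty device list")
  need <- function(nm) {
    if (is.null(devices[[nm]]))
      stop(sprintf("template '%s' requires device '%s'", template, nm))
    devices[[nm]]
  }
  steps <- list()
  add <- function(action, branch, device, placement = NULL) {
    steps[[length(steps) + 1L]] <<- procedure_step(
      step = length(steps) + 1L, action = action, branch = branch,
      device = device, pressure_atm = device$pressure_atm,
      placement = placement)
  }
  has_kbi <- !is.null(devices$kbi_mv) && !is.null(devices$kbi_sb)
  if (template == "provisional") {
    add("stent", "MV", need("mv_stent"))
    add("pot", "MV", need("pot_balloon"))
    add("sb_open", "SB", need("sb_balloon"))
    if (has_kbi) {
      add("kbi", "MV", devices$kbi_mv)
      steps[[length(steps)]]$device_sb <- devices$kbi_sb
    }
  } else if (template %in% c("TAP", "TAP_long_protrusion")) {
    protrusion <- if (template == "TAP_long_protrusion") 3.0 else 1.0
    add("stent", "MV", need("mv_stent"))
    add("pot", "MV", need("pot_balloon"))
    if (!is.null(devices$sb_balloon)) add("sb_open", "SB", devices$sb_balloon)
    add("stent", "SB", need("sb_stent"),
        placement = list(mode = "protrusion", value_mm = protrusion))
    kmv <- if (has_kbi) devices$kbi_mv else need("pot_balloon")
    ksb <- if (has_kbi) devices$kbi_sb else need("sb_stent")
    add("kbi", "MV", kmv); steps[[length(steps)]]$device_sb <- ksb
  } else { # culotte: SB stent first, protruding into the proximal MV
    add("stent", "SB", need("sb_stent"),
        placement = list(mode = "protrusion", value_mm = 6.0))
    add("pot", "MV", need("pot_balloon"))
    add("sb_open", "MV", need("sb_balloon"))  # recross MV struts
    add("stent", "MV", need("mv_stent"))
    add("pot", "MV", need("pot_balloon"),
        placement = list(mode = "relative_to_step", reference_step = 2L,
                         value_mm = 0))
    if (has_kbi) {
      add("kbi", "MV", devices$kbi_mv)
      steps[[length(steps)]]$device_sb <- devices$kbi_sb
    }
  }
  structure(list(template = template, steps = steps),
            class = "procedure_table")
}

## One procedure step record (shared schema with the JSON procedure files).
procedure_step <- function(step, action, branch, device, pressure_atm,
                           placement = NULL) {
  action <- match.arg(action, c("predilate", "stent", "pot", "sb_open",
                                "kbi", "postdilate"))
  if (is.null(pressure_atm) || pressure_atm <= 0)
    stop("step pressure must be > 0")
  list(step = as.integer(step), action = action,
       branch = match.arg(toupper(branch), c("MV", "SB")),
       device = device, pressure_atm = pressure_atm, placement = placement)
}

#' @export
print.procedure_table <- function(x, ...) {
  cat("Procedure (", x$template, "), ", length(x$steps), " steps:\n", sep = "")
  for (st in x$steps)
    cat(sprintf("  #%d %-9s %s  %s @ %g atm\n", st$step, st$action, st$branch,
                device_label(st$device), st$pressure_atm))
  invisible(x)
}

device_label <- function(d) {
  if (is.null(d)) return("-")
  if (d$kind == "stent")
    sprintf("%s %.2g x %g mm", d$preset, d$diameter_mm, d$length_mm)
  else sprintf("%s balloon %.2g x %g mm", d$compliance_class, d$diameter_mm,
               d$length_mm)
}

## --- exports --------------------------------------------------------------

#' Export a synthetic anatomy (STL surfaces, centerline CSV, params JSON)
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param dir output directory (created if needed).
#' @param h mesh resolution, mm.
#' @return character vector of written paths, invisibly.
#' @export
write_anatomy <- function(anatomy, dir, h = 0.4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (surf in c("lumen", "wall")) {
    m <- anatomy_mesh(anatomy, surf, h = h)
    p <- file.path(dir, paste0(surf, ".stl"))
    write_stl_ascii(m$mesh, p, name = surf)
    paths <- c(paths, p)
  }
  for (br in c("mv", "sb")) {
    b <- anatomy[[br]]
    df <- data.frame(x = b$centerline[, 1L], y = b$centerline[, 2L],
                     z = b$centerline[, 3L], arclength = b$s)
    p <- file.path(dir, paste0("centerline_", br, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "params.json")
  echo <- anatomy$params
  echo$stenoses <- as.list(echo$stenoses)
  jsonlite::write_json(echo, p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, p))
}

#' Export an OCT pullback (per-frame CSV + JSON manifest)
#'
#' One CSV per frame with columns angle_deg, lumen_radius_mm,
#' outer_radius_mm (NA inside missing arcs), tissue_label.
#'
#' @param pullback an `oct_pullback`.
#' @param dir output directory.
#' @return manifest path, invisibly.
#' @export
write_pullback <- function(pullback, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(pullback$frames)) {
    fr <- pullback$frames[[i]]
    tissue <- rep(NA_character_, length(fr$angles_deg))
    for (k in seq_len(nrow(fr$composition)))
      tissue[angle_in_arc(fr$angles_deg, fr$composition$start_deg[k],
                          fr$composition$end_deg[k])] <-
        fr$composition$tissue[k]
    utils::write.csv(
      data.frame(angle_deg = fr$angles_deg,
                 lumen_radius_mm = fr$lumen_radius,
                 outer_radius_mm = fr$outer_radius, tissue_label = tissue),
      file.path(dir, sprintf("frame_%04d.csv", i)), row.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n_frames = length(pullback$frames),
                            frame_spacing_mm = pullback$frame_spacing,
                            branch = pullback$branch,
                            carina_frame_index = pullback$carina_frame_index),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
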