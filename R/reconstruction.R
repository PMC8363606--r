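#' @title 3D reconstruction of the bifurcation from biplane + OCT
#' @description Rebuilds the bifurcation lumen and wall from two angiographic
#'   projection curves plus OCT pullbacks: centerline fusion from two views,
#'   carina-referenced alignment of frames with rotation-minimizing frames,
#'   the outer-border completion/discard rules (interpolate when less than
#'   180 degrees of the circumference is lost, discard beyond), branch
#'   lofting and implicit branch merging.
#' @name reconstruction
NULL

#' Fuse two projection curves into a 3D centerline
#'
#' Both views are parallel projections in planes containing the table (x)
#' axis, so a 3D point's axial coordinate is preserved in each view. Points
#' are paired on a common axial grid and the two in-plane equations
#' w_view . (y, z) = v solved per sample.
#'
#' @param curve_a,curve_b `projection_curve` objects (see
#'   [project_to_planes]).
#' @param n number of axial samples.
#' @param branch branch label stored on the result.
#' @param carina_arclength optional known carina arclength (mm) stored on the
#'   result.
#' @return object of class `centerline`: `points` (n x 3), `s` (cumulative
#'   arclength), `branch`, `carina_arclength`.
#' @export
centerline_from_biplane <- function(curve_a, curve_b, n = 200L,
                                    branch = "MV",
                                    carina_arclength = NA_real_) {
  stopifnot(inherits(curve_a, "projection_curve"),
            inherits(curve_b, "projection_curve"))
  if (abs(curve_a$view_angle - curve_b$view_angle) < 30)
    stop("near-parallel views: angiographic planes must be >= 30 degrees apart")
  ax_a <- range(curve_a$points[, 1L])
  ax_b <- range(curve_b$points[, 1L])
  len_a <- diff(ax_a); len_b <- diff(ax_b)
  if (abs(len_a - len_b) > 0.2 * max(len_a, len_b))
    warning("projection curves differ in axial extent by more than 20%; using best-fit overlap")
  lo <- max(ax_a[1L], ax_b[1L]); hi <- min(ax_a[2L], ax_b[2L])
  if (hi <= lo) stop("projection curves do not overlap axially")
  x <- seq(lo, hi, length.out = n)
  va <- stats::approx(curve_a$points[, 1L], curve_a$points[, 2L], xout = x)$y
  vb <- stats::approx(curve_b$points[, 1L], curve_b$points[, 2L], xout = x)$y
  wa <- curve_a$plane$w[2:3]
  wb <- curve_b$plane$w[2:3]
  M <- rbind(wa, wb)
  yz <- t(solve(M, rbind(va, vb)))
  pts <- cbind(x, yz)
  new_centerline(pts, branch, carina_arclength)
}

new_centerline <- function(pts, branch = "MV", carina_arclength = NA_real_) {
  keep <- c(TRUE, rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) > 1e-20)
  pts <- pts[keep, , drop = FALSE]
  structure(list(points = pts, s = cumulative_arclength(pts),
                 branch = toupper(branch),
                 carina_arclength = carina_arclength),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("Centerline (", x$branch, "): ", nrow(x$points), " points, ",
      round(max(x$s), 2), " mm", sep = "")
  if (!is.na(x$carina_arclength))
    cat(", carina at", x$carina_arclength, "mm")
  cat("\n")
  invisible(x)
}

#' Centerline of a synthetic anatomy branch (ground-truth accessor)
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param branch "MV" or "SB".
#' @return a `centerline` object.
#' @export
anatomy_centerline <- function(anatomy, branch = "MV") {
  b <- anat_branch(anatomy, branch)
  car <- if (toupper(branch) == "MV") anatomy$carina$arclength else 0
  new_centerline(b$centerline, branch, car)
}

#' Complete or discard an OCT frame with missing outer-border arcs
#'
#' If the outer border is unidentifiable over more than 180 degrees of the
#' circumference the frame is flagged DISCARD; at or below 180 degrees the
#' missing spans are filled by periodic spline interpolation through the
#' visible border (exactly 180 degrees is treated as interpolable).
#'
#' @param frame an `oct_frame`.
#' @return the frame, outer border completed, with attribute `discard`
#'   (logical) and `missing_deg` (total missing arc).
#' @export
complete_outer_contour <- function(frame) {
  stopifnot(inherits(frame, "oct_frame"))
  ang <- frame$angles_deg
  nbin <- length(ang)
  if (!is.null(frame$missing_arcs) && nrow(frame$missing_arcs) >= 0) {
    missing_deg <- sum((frame$missing_arcs[, 2L] - frame$missing_arcs[, 1L]) %% 360)
  } else {
    missing_deg <- sum(is.na(frame$outer_radius)) * 360 / nbin
  }
  out <- frame
  attr(out, "missing_deg") <- missing_deg
  if (missing_deg > 180) {
    attr(out, "discard") <- TRUE
    return(out)
  }
  attr(out, "discard") <- FALSE
  na <- is.na(frame$outer_radius)
  if (any(na)) {
    vis <- which(!na)
    x <- ang[vis]; y <- frame$outer_radius[vis]
    f <- stats::splinefun(c(x, x[1L] + 360), c(y, y[1L]), method = "periodic")
    miss_ang <- ang[na]
    shift <- ifelse(miss_ang < x[1L], miss_ang + 360, miss_ang)
    out$outer_radius[na] <- f(shift)
  }
  out$missing_arcs <- matrix(numeric(), 0L, 2L)
  out
}

#' Align an OCT pullback along a centerline
#'
#' Frame i is placed at arclength carina_arclength + (carina_index - i) *
#' spacing (frames are ordered distal to proximal), so the carina frame maps
#' exactly onto the carina arclength. Frames are oriented with
#' rotation-minimizing frames along the centerline; outer borders are first
#' passed through [complete_outer_contour] and DISCARD frames dropped from
#' the ring stacks (kept in the discard log).
#'
#' @param pullback an `oct_pullback`.
#' @param centerline a `centerline` with `carina_arclength` set.
#' @return object of class `positioned_frames`: per-frame arclength `s`,
#'   lumen/outer ring stacks (n_angle x 3 matrices), `discard` log,
#'   `centerline`, `angles_deg`.
#' @export
align_pullback <- function(pullback, centerline) {
  stopifnot(inherits(pullback, "oct_pullback"),
            inherits(centerline, "centerline"))
  if (is.na(centerline$carina_arclength))
    stop("centerline carina_arclength must be set")
  nfr <- length(pullback$frames)
  s_frames <- centerline$carina_arclength +
    (pullback$carina_frame_index - seq_len(nfr)) * pullback$frame_spacing
  inside <- s_frames >= min(centerline$s) & s_frames <= max(centerline$s)
  if (!all(inside))
    warning(sprintf("%d frame(s) extend beyond the centerline; truncated",
                    sum(!inside)))
  completed <- lapply(pullback$frames, complete_outer_contour)
  discard <- vapply(completed, function(f) attr(f, "discard"), logical(1L))
  keep <- inside & !discard
  s_f <- sort(unique(c(centerline$s, s_frames[keep])))
  s_f <- s_f[c(TRUE, diff(s_f) > 1e-9)]
  cl_f <- resample_polyline(centerline$points, centerline$s, s_f)
  fr3 <- rm_frames(cl_f)
  ang_rad <- pullback$frames[[1L]]$angles_deg * pi / 180
  ring_of <- function(center, n1, n2, radii) {
    center[rep(1L, length(ang_rad)), , drop = FALSE] +
      radii * cos(ang_rad) * n1[rep(1L, length(ang_rad)), , drop = FALSE] +
      radii * sin(ang_rad) * n2[rep(1L, length(ang_rad)), , drop = FALSE]
  }
  idxs <- vapply(s_frames[keep], function(v) which.min(abs(s_f - v)),
                 integer(1L))
  lum <- out <- vector("list", sum(keep))
  kk <- which(keep)
  for (m in seq_along(kk)) {
    i <- kk[m]; gi <- idxs[m]
    lum[[m]] <- ring_of(cl_f[gi, , drop = FALSE], fr3$n1[gi, , drop = FALSE],
                        fr3$n2[gi, , drop = FALSE],
                        completed[[i]]$lumen_radius)
    out[[m]] <- ring_of(cl_f[gi, , drop = FALSE], fr3$n1[gi, , drop = FALSE],
                        fr3$n2[gi, , drop = FALSE],
                        completed[[i]]$outer_radius)
  }
  structure(list(s = s_frames[keep], rings_lumen = lum, rings_outer = out,
                 frame_index = kk,
                 discard = data.frame(frame = seq_len(nfr),
                                      missing_deg = vapply(completed,
                                        function(f) attr(f, "missing_deg"),
                                        numeric(1L)),
                                      discarded = discard,
                                      truncated = !inside),
                 centerline = centerline,
                 angles_deg = pullback$frames[[1L]]$angles_deg,
                 branch = pullback$branch),
            class = "positioned_frames")
}

#' Loft positioned OCT frames into branch surfaces
#'
#' Ruled surfaces through corresponding angular samples of consecutive
#' non-discarded frames (a discarded interior frame simply lengthens the
#' span); capped ends make the tubes watertight.
#'
#' @param positioned a `positioned_frames` object.
#' @return list with `inner`/`outer` meshes, the ring stacks ordered
#'   proximal to distal, per-ring arclength `s`, and the centerline.
#' @export
loft_branch <- function(positioned) {
  stopifnot(inherits(positioned, "positioned_frames"))
  if (length(positioned$rings_lumen) < 2L)
    stop("at least 2 usable frames are required for lofting")
  ord <- order(positioned$s)
  structure(list(inner = tube_mesh(positioned$rings_lumen[ord]),
                 outer = tube_mesh(positioned$rings_outer[ord]),
                 rings_lumen = positioned$rings_lumen[ord],
                 rings_outer = positioned$rings_outer[ord],
                 s = positioned$s[ord],
                 centerline = positioned$centerline,
                 branch = positioned$branch),
            class = "lofted_branch")
}

## Planar 3D polygon area: half the norm of the summed cross products about
## the centroid.
ring_area <- function(ring) {
  c0 <- colMeans(ring)
  p <- sweep(ring, 2L, c0)
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  cx <- p[, 2L] * q[, 3L] - p[, 3L] * q[, 2L]
  cy <- p[, 3L] * q[, 1L] - p[, 1L] * q[, 3L]
  cz <- p[, 1L] * q[, 2L] - p[, 2L] * q[, 1L]
  sqrt(sum(cx)^2 + sum(cy)^2 + sum(cz)^2) / 2
}

#' Merge lofted MV and SB branches into a bifurcation geometry
#'
#' The two branch tubes are united implicitly (marching tetrahedra over the
#' min of the two tube distance fields built from per-ring area-equivalent
#' radii), giving a single watertight lumen and wall. The SB ostium boundary
#' curve is traced where the SB surface lines exit the MV lumen and stored
#' with its enclosed area.
#'
#' @param mv,sb `lofted_branch` objects.
#' @param carina_point 3D carina location (defaults to the SB centerline
#'   origin).
#' @param h merge grid resolution, mm.
#' @return object of class `bifurcation_geometry`.
#' @export
merge_branches <- function(mv, sb, carina_point = NULL, h = 0.4) {
  stopifnot(inherits(mv, "lofted_branch"), inherits(sb, "lofted_branch"))
  if (is.null(carina_point)) carina_point <- sb$centerline$points[1L, ]
  req <- sqrt(vapply(mv$rings_lumen, ring_area, numeric(1L)) / pi)
  res <- sqrt(vapply(sb$rings_lumen, ring_area, numeric(1L)) / pi)
  cl_mv <- resample_polyline(mv$centerline$points, mv$centerline$s, mv$s)
  cl_sb <- resample_polyline(sb$centerline$points, sb$centerline$s, sb$s)
  ## branches must intersect near the carina
  d_start <- tube_field(cl_sb[1L, , drop = FALSE], cl_mv, req)
  if (d_start > 0)
    stop("MV and SB surfaces do not intersect near the carina")
  rwq <- sqrt(vapply(mv$rings_outer, ring_area, numeric(1L)) / pi)
  rws <- sqrt(vapply(sb$rings_outer, ring_area, numeric(1L)) / pi)
  lum_field <- function(p) pmin(tube_field(p, cl_mv, req),
                                tube_field(p, cl_sb, res))
  wall_field <- function(p) pmin(tube_field(p, cl_mv, rwq),
                                 tube_field(p, cl_sb, rws))
  allpts <- rbind(cl_mv, cl_sb)
  marg <- max(rwq, rws) + 2 * h
  lo <- apply(allpts, 2L, min) - marg
  hi <- apply(allpts, 2L, max) + marg
  lum <- implicit_surface(lum_field, lo, hi, h)
  wal <- implicit_surface(wall_field, lo, hi, h)
  ## per-branch voxel volumes on the same grid
  g <- as.matrix(expand.grid(x = lum$grid$xs, y = lum$grid$ys,
                             z = lum$grid$zs))
  vol_mv <- sum(tube_field(g, cl_mv, req) < 0) * h^3
  vol_sb <- sum(tube_field(g, cl_sb, res) < 0) * h^3
  ostium <- trace_ostium(sb, cl_mv, req)
  structure(list(lumen = lum$mesh, wall = wal$mesh,
                 volume_mm3 = lum$volume_mm3,
                 branch_volumes_mm3 = c(MV = vol_mv, SB = vol_sb),
                 mv = mv, sb = sb, carina_point = carina_point,
                 ostium = ostium),
            class = "bifurcation_geometry")
}

## Trace where each SB surface line (fixed angle across frames) exits the MV
## lumen; returns the 3D boundary curve and its best-fit-plane area.
trace_ostium <- function(sb, cl_mv, r_mv) {
  na <- nrow(sb$rings_lumen[[1L]])
  nf <- length(sb$rings_lumen)
  pts <- matrix(NA_real_, na, 3L)
  for (j in seq_len(na)) {
    line <- t(vapply(sb$rings_lumen, function(r) r[j, ], numeric(3L)))
    d <- tube_field(line, cl_mv, r_mv)
    cross <- which(d[-1L] >= 0 & d[-nf] < 0)
    if (length(cross) == 0L) next
    i <- cross[1L]
    t0 <- d[i] / (d[i] - d[i + 1L])
    pts[j, ] <- line[i, ] + t0 * (line[i + 1L, ] - line[i, ])
  }
  ok <- stats::complete.cases(pts)
  pts <- pts[ok, , drop = FALSE]
  if (nrow(pts) < 3L) return(list(curve = pts, area_mm2 = NA_real_))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  uv <- sweep(pts, 2L, ctr) %*% sv$v[, 1:2]
  list(curve = pts, area_mm2 = polygon_area(uv[, 1L], uv[, 2L]))
}

#' @export
print.bifurcation_geometry <- function(x, ...) {
  cat("Bifurcation geometry: lumen", nrow(x$lumen$triangles), "tris, volume",
      round(x$volume_mm3, 1), "mm^3, ostium area",
      round(x$ostium$area_mm2, 2), "mm^2\n")
  invisible(x)
}

#' Per-slice area and area-equivalent diameter along a branch
#'
#' Cross-sections are the lofted OCT rings (perpendicular to the centerline
#' by construction); area from the ring polygon, diameter = 2 sqrt(A/pi),
#' resampled at the requested spacing. Slices outside the lofted extent are
#' marked absent (NA).
#'
#' @param geometry a `bifurcation_geometry` or `lofted_branch`.
#' @param spacing mm.
#' @param branch "MV" or "SB" (for a merged geometry).
#' @return data.frame: `arclength_mm`, `area_mm2`, `diameter_mm`, `present`.
#' @export
slice_profile <- function(geometry, spacing = 0.5, branch = "MV") {
  if (spacing <= 0) stop("spacing must be > 0")
  br <- if (inherits(geometry, "lofted_branch")) geometry
        else if (toupper(branch) == "MV") geometry$mv else geometry$sb
  areas <- vapply(br$rings_lumen, ring_area, numeric(1L))
  s_out <- seq(min(br$s), max(br$s), by = spacing)
  a_out <- stats::approx(br$s, areas, xout = s_out)$y
  data.frame(arclength_mm = s_out, area_mm2 = a_out,
             diameter_mm = 2 * sqrt(a_out / pi),
             present = !is.na(a_out))
}
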