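#' @title 3D stent reconstruction from OCT strut detections
#' @description Rebuilds a deployed stent from per-frame strut point
#'   detections: the points are flattened to a 2D (axial, circumferential)
#'   surface, registered to the 2D stent design pattern (periodic rigid
#'   registration plus bounded per-ring axial adjustment), connected with the
#'   pattern's strut/link topology, wrapped back onto the lumen centerline,
#'   and given strut volume. Strut "detection" itself is simulated by
#'   sampling a deployed stent; image-based segmentation is out of scope.
#' @name stent-recon
NULL

#' Simulate OCT strut detections from a deployed stent
#'
#' Samples the deployed stent nodes into frames at the given spacing: each
#' node is assigned to its nearest frame and recorded as (angle, radial
#' distance) in that frame, mirroring how struts appear as points in OCT
#' cross-sections.
#'
#' @param geometry a deployed `stent_geometry` (see
#'   [deployed_stent_geometry]) with node arclengths.
#' @param centerline the branch `centerline`.
#' @param frame_spacing mm (default 0.2).
#' @return object of class `strut_cloud`: data.frame `points` (frame,
#'   angle_deg, radius_mm), `frame_s` (axial positions), `frame_spacing`.
#' @export
simulate_strut_detections <- function(geometry, centerline,
                                      frame_spacing = 0.2) {
  stopifnot(!is.null(geometry$arclength))
  s_node <- geometry$arclength
  f0 <- floor(min(s_node) / frame_spacing)
  frame_s <- seq(f0 * frame_spacing, max(s_node) + frame_spacing / 2,
                 by = frame_spacing)
  fr_idx <- vapply(s_node, function(s) which.min(abs(frame_s - s)),
                   integer(1L))
  s_f <- sort(unique(c(centerline$s, frame_s)))
  s_f <- s_f[c(TRUE, diff(s_f) > 1e-9)]
  cl_f <- resample_polyline(centerline$points, centerline$s, s_f)
  frames3 <- rm_frames(cl_f)
  gidx <- vapply(frame_s, function(v) which.min(abs(s_f - v)), integer(1L))
  ang <- radius <- numeric(length(s_node))
  for (k in seq_along(s_node)) {
    gi <- gidx[fr_idx[k]]
    d <- geometry$nodes[k, ] - cl_f[gi, ]
    x1 <- sum(d * frames3$n1[gi, ])
    x2 <- sum(d * frames3$n2[gi, ])
    ang[k] <- (atan2(x2, x1) * 180 / pi) %% 360
    radius[k] <- sqrt(x1^2 + x2^2)
  }
  structure(list(points = data.frame(frame = fr_idx, angle_deg = ang,
                                     radius_mm = radius),
                 frame_s = frame_s, frame_spacing = frame_spacing),
            class = "strut_cloud")
}

#' Flatten a strut point cloud to 2D
#'
#' Unrolls each frame's points to (axial, circumferential arc) coordinates,
#' arc = angle * mean frame radius, with the local period 2 pi r stored per
#' frame. Invertible given the same radii.
#'
#' @param cloud a `strut_cloud`.
#' @param frame_radius optional per-frame lumen radius; defaults to the mean
#'   detected strut radius per frame (all frames pooled where empty).
#' @return object of class `unrolled_cloud`: `points` (z_mm, arc_mm, frame),
#'   `period` (per frame), `frame_s`.
#' @export
unroll <- function(cloud, frame_radius = NULL) {
  stopifnot(inherits(cloud, "strut_cloud"))
  nf <- length(cloud$frame_s)
  if (is.null(frame_radius)) {
    frame_radius <- rep(mean(cloud$points$radius_mm), nf)
    agg <- tapply(cloud$points$radius_mm, cloud$points$frame, mean)
    frame_radius[as.integer(names(agg))] <- agg
  }
  if (length(frame_radius) != nf || any(is.na(frame_radius)))
    stop("a radius is required for every frame")
  r <- frame_radius[cloud$points$frame]
  structure(list(points = data.frame(
    z_mm = cloud$frame_s[cloud$points$frame],
    arc_mm = cloud$points$angle_deg * pi / 180 * r,
    frame = cloud$points$frame),
    period = 2 * pi * frame_radius, frame_s = cloud$frame_s,
    frame_radius = frame_radius),
    class = "unrolled_cloud")
}

## 2D pattern nodes of a design at a common unrolling radius:
## (z, arc) with period 2 pi r_ref.
pattern_2d <- function(design, r_ref) {
  g <- build_nominal_stent(design)
  z <- g$nodes[, 1L]
  arc <- g$angle_deg * pi / 180 * r_ref
  list(z = z, arc = arc, period = 2 * pi * r_ref, edges = g$edges,
       edge_type = g$edge_type, ring = g$ring, angle_deg = g$angle_deg,
       geometry = g)
}

## Circular (periodic) difference in arc coordinates.
circ_diff <- function(a, b, period) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Register a 2D strut cloud to the stent design pattern
#'
#' Rigid 2D registration (axial shift + periodic circumferential rotation,
#' found by grid search over rotation bins refined with local optimization)
#' minimizing summed nearest-neighbor distance, followed by one-to-one
#' point-node assignment under a distance gate (greedy by increasing
#' distance) and a bounded per-ring axial offset refinement. Edges are
#' inherited from the pattern topology between matched nodes.
#'
#' @param cloud2d an `unrolled_cloud`.
#' @param design the [stent_design] used as the pattern reference.
#' @param gate_mm assignment distance gate in unrolled coordinates.
#' @param residual_threshold mm; above this mean residual the match is
#'   flagged low confidence.
#' @return object of class `stent_graph_match`: `assignment` (point ->
#'   pattern node), matched `edges`, `residual_mm`, recovered `rotation_deg`
#'   and `axial_shift_mm`, `low_confidence` flag, `missing_nodes`.
#' @export
register_pattern <- function(cloud2d, design, gate_mm = 0.3,
                             residual_threshold = 0.25) {
  stopifnot(inherits(cloud2d, "unrolled_cloud"))
  pts <- cloud2d$points
  r_ref <- mean(cloud2d$frame_radius)
  ## renormalize each frame's arc to the common reference circumference so
  ## the periodic rigid registration is well posed on tapered lumens
  pts$arc_mm <- pts$arc_mm / cloud2d$frame_radius[pts$frame] * r_ref
  pat <- pattern_2d(design, r_ref)
  n_nodes <- length(pat$z)
  if (nrow(pts) < 0.5 * n_nodes)
    stop("fewer detections than half the pattern nodes; cannot register")
  period <- pat$period

  cost <- function(par) {
    dz <- par[1L]; da <- par[2L]
    zz <- pat$z + dz
    aa <- (pat$arc + da) %% period
    tot <- 0
    for (i in seq_len(nrow(pts))) {
      d2 <- (pts$z_mm[i] - zz)^2 +
        circ_diff(pts$arc_mm[i], aa, period)^2
      tot <- tot + min(d2)
    }
    tot
  }
  z_shift0 <- mean(range(pts$z_mm)) - mean(range(pat$z))
  nbin <- 2L * design$crowns_per_ring
  grid <- (seq_len(nbin) - 1L) / nbin * period
  c0 <- vapply(grid, function(g) cost(c(z_shift0, g)), numeric(1L))
  best <- grid[which.min(c0)]
  opt <- stats::optim(c(z_shift0, best), cost, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  dz <- opt$par[1L]; da <- opt$par[2L]

  node_z <- pat$z + dz
  node_arc <- (pat$arc + da) %% period
  ## bounded per-ring axial adjustment (foreshortening), +-20% of ring pitch
  pitch <- design$nominal_length / design$rings
  for (r in seq_len(design$rings)) {
    sel <- pat$ring == r
    dists <- vapply(which(sel), function(j) {
      d2 <- (pts$z_mm - node_z[j])^2 +
        circ_diff(pts$arc_mm, node_arc[j], period)^2
      i <- which.min(d2)
      pts$z_mm[i] - node_z[j]
    }, numeric(1L))
    ## mean, not median: averages out the frame-quantization of detections
    adj <- mean(dists[abs(dists) < pitch / 2])
    if (!is.finite(adj)) adj <- 0
    node_z[sel] <- node_z[sel] + max(-0.2 * pitch, min(0.2 * pitch, adj))
  }

  ## greedy one-to-one matching under the gate, by increasing distance
  cand <- list()
  for (j in seq_len(n_nodes)) {
    d <- sqrt((pts$z_mm - node_z[j])^2 +
              circ_diff(pts$arc_mm, node_arc[j], period)^2)
    ok <- which(d <= gate_mm)
    if (length(ok))
      cand[[length(cand) + 1L]] <- data.frame(pt = ok, node = j, d = d[ok])
  }
  assignment <- rep(NA_integer_, nrow(pts))
  node_used <- logical(n_nodes)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$d), ]
    for (i in seq_len(nrow(cand))) {
      p <- cand$pt[i]; nd <- cand$node[i]
      if (is.na(assignment[p]) && !node_used[nd]) {
        assignment[p] <- nd
        node_used[nd] <- TRUE
      }
    }
  }
  matched_nodes <- which(node_used)
  keep_e <- pat$edges[, 1L] %in% matched_nodes &
    pat$edges[, 2L] %in% matched_nodes
  res <- vapply(which(!is.na(assignment)), function(p) {
    j <- assignment[p]
    sqrt((pts$z_mm[p] - node_z[j])^2 +
         circ_diff(pts$arc_mm[p], node_arc[j], period)^2)
  }, numeric(1L))
  residual <- if (length(res)) mean(res) else Inf
  structure(list(assignment = assignment,
                 node_z = node_z, node_arc = node_arc, period = period,
                 edges = pat$edges[keep_e, , drop = FALSE],
                 edge_type = pat$edge_type[keep_e],
                 pattern = pat, design = design,
                 residual_mm = residual,
                 rotation_deg = (da / period * 360) %% 360,
                 axial_shift_mm = dz,
                 low_confidence = residual > residual_threshold,
                 missing_nodes = which(!node_used)),
            class = "stent_graph_match")
}

#' @export
print.stent_graph_match <- function(x, ...) {
  cat("Pattern match:", sum(!is.na(x$assignment)), "points matched,",
      length(x$missing_nodes), "pattern nodes missing, residual",
      round(x$residual_mm, 4), "mm",
      if (x$low_confidence) "(LOW CONFIDENCE)", "\n")
  invisible(x)
}

#' Wrap a matched 2D stent graph back onto the 3D lumen
#'
#' Matched pattern nodes are placed at their (arclength, angle) on the lumen
#' surface, offset inward by half a strut thickness; pattern edges become 3D
#' segments (polylines).
#'
#' @param match a `stent_graph_match`.
#' @param centerline the branch `centerline`.
#' @param lumen_radius function(s) giving lumen radius at arclength, or a
#'   data.frame with `arclength`/`r` columns.
#' @return a `stent_geometry` (state "reconstructed") containing only the
#'   matched nodes and edges.
#' @export
wrap_to_3d <- function(match, centerline, lumen_radius) {
  stopifnot(inherits(match, "stent_graph_match"))
  r_of <- if (is.function(lumen_radius)) lumen_radius
          else function(s) stats::approx(lumen_radius$arclength,
                                         lumen_radius$r, xout = s,
                                         rule = 2)$y
  used <- sort(unique(stats::na.omit(match$assignment)))
  s_node <- match$node_z[used]
  theta <- match$node_arc[used] / match$period * 2 * pi
  s_f <- sort(unique(c(centerline$s, s_node)))
  s_f <- s_f[c(TRUE, diff(s_f) > 1e-9)]
  cl_f <- resample_polyline(centerline$points, centerline$s, s_f)
  fr <- rm_frames(cl_f)
  gi <- vapply(s_node, function(v) which.min(abs(s_f - v)), integer(1L))
  rr <- r_of(s_node) - strut_thickness(match$design) / 2
  nodes <- cl_f[gi, , drop = FALSE] +
    rr * cos(theta) * fr$n1[gi, , drop = FALSE] +
    rr * sin(theta) * fr$n2[gi, , drop = FALSE]
  remap <- match(match$edges, used)
  edges <- matrix(remap, ncol = 2L)
  ok <- stats::complete.cases(edges)
  structure(list(nodes = nodes, edges = edges[ok, , drop = FALSE],
                 edge_type = match$edge_type[ok],
                 ring = match$pattern$ring[used],
                 angle_deg = (theta * 180 / pi) %% 360,
                 state = "reconstructed", design = match$design,
                 arclength = s_node, node_ids = used),
            class = "stent_geometry")
}

#' Add strut volume to a reconstructed stent graph
#'
#' Sweeps the strut cross-section along each edge as an n-gon prism with end
#' caps (watertight per strut). Zero-length edges are skipped with a warning.
#'
#' @param geometry a `stent_geometry`.
#' @param n_side facets around the strut (default 16).
#' @return a triangle mesh (all strut tubes combined).
#' @export
add_strut_volume <- function(geometry, n_side = 16L) {
  d <- strut_thickness(geometry$design)
  r <- d / 2
  meshes <- list()
  skipped <- 0L
  th <- seq(0, 2 * pi, length.out = n_side + 1L)[-(n_side + 1L)]
  for (k in seq_len(nrow(geometry$edges))) {
    a <- geometry$nodes[geometry$edges[k, 1L], ]
    b <- geometry$nodes[geometry$edges[k, 2L], ]
    ax <- b - a
    L <- sqrt(sum(ax^2))
    if (L < 1e-9) { skipped <- skipped + 1L; next }
    ax <- ax / L
    ref <- if (abs(ax[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    u <- ref - sum(ref * ax) * ax
    u <- u / sqrt(sum(u^2))
    v <- c(ax[2L] * u[3L] - ax[3L] * u[2L],
           ax[3L] * u[1L] - ax[1L] * u[3L],
           ax[1L] * u[2L] - ax[2L] * u[1L])
    ring_a <- sweep(r * (cos(th) %o% u + sin(th) %o% v), 2L, a, "+")
    ring_b <- sweep(r * (cos(th) %o% u + sin(th) %o% v), 2L, b, "+")
    meshes[[length(meshes) + 1L]] <- tube_mesh(list(ring_a, ring_b),
                                               cap = TRUE)
  }
  if (skipped > 0L)
    warning(sprintf("%d zero-length edge(s) skipped", skipped))
  if (length(meshes) == 0L) stop("no edges to sweep")
  nv <- 0L
  verts <- list(); tris <- list()
  for (m in meshes) {
    verts[[length(verts) + 1L]] <- m$vertices
    tris[[length(tris) + 1L]] <- m$triangles + nv
    nv <- nv + nrow(m$vertices)
  }
  make_mesh(do.call(rbind, verts), do.call(rbind, tris))
}

#' Write a strut point cloud to CSV
#'
#' @param cloud a `strut_cloud`.
#' @param path output path (columns frame, angle_deg, radius_mm).
#' @return `path`, invisibly.
#' @export
write_strut_cloud <- function(cloud, path) {
  utils::write.csv(cloud$points, path, row.names = FALSE)
  invisible(path)
}
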