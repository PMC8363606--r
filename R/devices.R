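#' @title Parametric stent and balloon devices
#' @description Ring-and-link stent patterns synthesized parametrically (the
#'   proprietary laser-cut/wire patterns are not public; presets encode
#'   family, strut section and alloy only), radial-displacement crimping,
#'   positioning and bending along a centerline with rotation-minimizing
#'   frames, and a closed-form membrane stand-in for balloon compliance.
#' @name devices
NULL

#' Pressure unit conversion
#'
#' @param p pressure in atm.
#' @return pressure in MPa (1 atm = 0.101325 MPa).
#' @export
atm_to_mpa <- function(p) p * 0.101325

#' Parametric stent design
#'
#' @param rings number of zig-zag rings.
#' @param crowns_per_ring crowns (peaks) per ring.
#' @param links_per_ring_pair connectors between adjacent rings.
#' @param strut_section list(shape = "circular", diameter_mm = ...) or
#'   list(shape = "rectangular", width_mm = ..., thickness_mm = ...).
#' @param alloy alloy name in the material table ("MP35N", "PtCr", ...).
#' @param core_alloy optional core alloy for shell-core wire (Onyx-like);
#'   `core_area_fraction` of the section area (default 0.25).
#' @param nominal_diameter,nominal_length mm.
#' @param family "wire" or "laser_cut".
#' @param core_area_fraction fraction of section area taken by the core.
#' @return object of class `stent_design`.
#' @export
stent_design <- function(rings = 10L, crowns_per_ring = 8L,
                         links_per_ring_pair = 2L,
                         strut_section = list(shape = "circular",
                                              diameter_mm = 0.091),
                         alloy = "MP35N", core_alloy = NULL,
                         nominal_diameter = 3.0, nominal_length = 18,
                         family = c("wire", "laser_cut"),
                         core_area_fraction = 0.25) {
  family <- match.arg(family)
  stopifnot(rings >= 1L, crowns_per_ring >= 1L, links_per_ring_pair >= 1L,
            nominal_diameter > 0, nominal_length > 0)
  structure(list(rings = as.integer(rings),
                 crowns_per_ring = as.integer(crowns_per_ring),
                 links_per_ring_pair = as.integer(links_per_ring_pair),
                 strut_section = strut_section, alloy = alloy,
                 core_alloy = core_alloy,
                 core_area_fraction = core_area_fraction,
                 nominal_diameter = nominal_diameter,
                 nominal_length = nominal_length, family = family),
            class = "stent_design")
}

#' Named stent design presets
#'
#' Representative (not manufacturer) patterns: `integrity_like` (MP35N wire,
#' circular strut), `onyx_like` (shell-core MP35N/Pt-Ir wire), `synergy_like`
#' (Pt-Cr laser-cut, rectangular strut).
#'
#' @param preset preset name.
#' @param nominal_diameter,nominal_length mm.
#' @return a [stent_design].
#' @export
stent_preset <- function(preset = c("integrity_like", "onyx_like",
                                    "synergy_like"),
                         nominal_diameter = 3.0, nominal_length = 18) {
  preset <- match.arg(preset)
  rings <- max(4L, round(nominal_length / 1.6))
  switch(preset,
    integrity_like = stent_design(rings, 8L, 2L,
      list(shape = "circular", diameter_mm = 0.091), "MP35N",
      nominal_diameter = nominal_diameter, nominal_length = nominal_length,
      family = "wire"),
    onyx_like = stent_design(rings, 8L, 2L,
      list(shape = "circular", diameter_mm = 0.081), "MP35N",
      core_alloy = "PtIr", nominal_diameter = nominal_diameter,
      nominal_length = nominal_length, family = "wire"),
    synergy_like = stent_design(rings, 8L, 2L,
      list(shape = "rectangular", width_mm = 0.097, thickness_mm = 0.074),
      "PtCr", nominal_diameter = nominal_diameter,
      nominal_length = nominal_length, family = "laser_cut"))
}

#' Strut cross-section area
#'
#' @param design a [stent_design].
#' @return area, mm^2.
#' @export
strut_area <- function(design) {
  s <- design$strut_section
  if (s$shape == "circular") pi * (s$diameter_mm / 2)^2
  else s$width_mm * s$thickness_mm
}

#' Strut radial thickness (profile height)
#'
#' @param design a [stent_design].
#' @return mm.
#' @export
strut_thickness <- function(design) {
  s <- design$strut_section
  if (s$shape == "circular") s$diameter_mm else s$thickness_mm
}

#' Effective elastic modulus of a (possibly shell-core) strut
#'
#' Area-weighted modulus of shell and core alloys.
#'
#' @param design a [stent_design].
#' @param table a [material_table].
#' @return modulus, MPa.
#' @export
effective_strut_modulus <- function(design, table = material_table()) {
  E_shell <- table$alloys[[design$alloy]]$elastic_modulus * 1000
  if (is.null(design$core_alloy)) return(E_shell)
  E_core <- table$alloys[[design$core_alloy]]$elastic_modulus * 1000
  f <- design$core_area_fraction
  (1 - f) * E_shell + f * E_core
}

#' Build the nominal stent geometry
#'
#' Nodes on a cylinder of the nominal diameter: per ring, peaks and valleys
#' alternate around the circumference (2 x crowns nodes per ring), joined by
#' crown arms; adjacent rings are connected valley-to-peak by
#' `links_per_ring_pair` links.
#'
#' @param design a [stent_design].
#' @return object of class `stent_geometry`: `nodes` (n x 3 mm), `edges`
#'   (m x 2 indices), `edge_type` ("crown_arm"/"link"), `ring` and
#'   `angle_deg` per node, `state` tag, and the design.
#' @export
build_nominal_stent <- function(design) {
  stopifnot(inherits(design, "stent_design"))
  nc <- design$crowns_per_ring
  nr <- design$rings
  npr <- 2L * nc                       # nodes per ring (peaks + valleys)
  ring_pitch <- design$nominal_length / nr
  crown_h <- ring_pitch * 0.45
  R <- design$nominal_diameter / 2
  ang <- (seq_len(npr) - 1L) * 360 / npr
  nodes <- NULL; ring_id <- integer(); ang_deg <- numeric()
  for (r in seq_len(nr)) {
    z0 <- (r - 0.5) * ring_pitch
    zz <- z0 + ifelse(seq_len(npr) %% 2L == 1L, -crown_h / 2, crown_h / 2)
    th <- ang * pi / 180
    nodes <- rbind(nodes, cbind(zz, R * cos(th), R * sin(th)))
    ring_id <- c(ring_id, rep(r, npr))
    ang_deg <- c(ang_deg, ang)
  }
  edges <- NULL; etype <- character()
  for (r in seq_len(nr)) {
    base <- (r - 1L) * npr
    j <- seq_len(npr); jn <- c(2:npr, 1L)
    edges <- rbind(edges, cbind(base + j, base + jn))
    etype <- c(etype, rep("crown_arm", npr))
  }
  ## links: connect a valley (even node, +crown_h/2, top of ring r) to the
  ## peak directly above it in ring r+1 (odd node, -crown_h/2)
  if (nr > 1L) {
    slots <- round(seq(1L, npr, length.out = design$links_per_ring_pair + 1L))
    slots <- unique(pmin(slots[seq_len(design$links_per_ring_pair)], npr))
    for (r in seq_len(nr - 1L)) {
      base <- (r - 1L) * npr
      for (sl in slots) {
        valley <- base + if (sl %% 2L == 0L) sl else (sl %% npr) + 1L
        peak_above <- r * npr + if (sl %% 2L == 1L) sl else (sl %% npr) + 1L
        edges <- rbind(edges, cbind(valley, peak_above))
        etype <- c(etype, "link")
      }
    }
  }
  ## normalize the axial span to the labeled stent length
  span <- max(nodes[, 1L]) - min(nodes[, 1L])
  nodes[, 1L] <- (nodes[, 1L] - min(nodes[, 1L])) *
    design$nominal_length / span
  structure(list(nodes = nodes, edges = edges, edge_type = etype,
                 ring = ring_id, angle_deg = ang_deg, state = "nominal",
                 design = design),
            class = "stent_geometry")
}

#' @export
print.stent_geometry <- function(x, ...) {
  cat("Stent geometry (", x$state, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges, ", x$design$rings, " rings\n", sep = "")
  invisible(x)
}

#' Is the stent strut graph connected?
#'
#' @param geometry a `stent_geometry`.
#' @return logical.
#' @export
stent_graph_connected <- function(geometry) {
  n <- nrow(geometry$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(geometry$edges))) {
    e <- geometry$edges[k, ]
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    adj[[e[2L]]] <- c(adj[[e[2L]]], e[1L])
  }
  seen <- logical(n)
  stack <- 1L; seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

#' Crimp a stent by radial displacement
#'
#' Pure radial scaling of all node radii to the target; axial coordinates,
#' angular ordering and topology are preserved (kinematically invertible).
#'
#' @param geometry a `stent_geometry` (nominal state).
#' @param target_diameter mm, 0 < target < nominal.
#' @return crimped `stent_geometry`.
#' @export
crimp <- function(geometry, target_diameter) {
  stopifnot(inherits(geometry, "stent_geometry"))
  nom <- geometry$design$nominal_diameter
  if (target_diameter <= 0 || target_diameter >= nom)
    stop("target diameter must be in (0, nominal)")
  f <- target_diameter / nom
  out <- geometry
  out$nodes[, 2:3] <- geometry$nodes[, 2:3] * f
  out$state <- "crimped"
  out
}

#' Position and bend a stent along a centerline
#'
#' Maps the stent's straight axis onto the centerline with rotation-minimizing
#' frames: a node at axial coordinate z, radius r, angle theta lands at
#' centerline(s0 + z) + r (cos(theta) n1 + sin(theta) n2). Cross-sections
#' remain planar and normal to the centerline.
#'
#' @param geometry a `stent_geometry`.
#' @param centerline a `centerline` object (see [centerline_from_biplane]) or
#'   list with `points` (n x 3) and `s` (arclength).
#' @param proximal_edge_arclength mm; where the proximal stent edge lands.
#' @param rotation_deg absolute circumferential rotation.
#' @return placed `stent_geometry`.
#' @export
position_and_bend <- function(geometry, centerline,
                              proximal_edge_arclength = 0, rotation_deg = 0) {
  stopifnot(inherits(geometry, "stent_geometry"))
  cl <- centerline$points
  s <- centerline$s
  zmin <- min(geometry$nodes[, 1L])
  zspan <- max(geometry$nodes[, 1L]) - zmin
  if (proximal_edge_arclength < min(s) ||
      proximal_edge_arclength + zspan > max(s))
    stop("stent placement extends beyond the centerline")
  s_node <- proximal_edge_arclength + (geometry$nodes[, 1L] - zmin)
  ## densified frames for smooth transport
  s_f <- sort(unique(c(s, s_node)))
  s_f <- s_f[c(TRUE, diff(s_f) > 1e-9)]
  cl_f <- resample_polyline(cl, s, s_f)
  fr <- rm_frames(cl_f)
  idx <- vapply(s_node, function(v) which.min(abs(s_f - v)), integer(1L))
  r_node <- sqrt(geometry$nodes[, 2L]^2 + geometry$nodes[, 3L]^2)
  th <- atan2(geometry$nodes[, 3L], geometry$nodes[, 2L]) +
    rotation_deg * pi / 180
  out <- geometry
  out$nodes <- cl_f[idx, , drop = FALSE] +
    r_node * cos(th) * fr$n1[idx, , drop = FALSE] +
    r_node * sin(th) * fr$n2[idx, , drop = FALSE]
  out$state <- "placed"
  out$arclength <- s_node
  out$angle_deg <- (geometry$angle_deg + rotation_deg) %% 360
  out
}

#' Balloon specification
#'
#' @param nominal_diameter,length mm.
#' @param compliance_class "compliant", "semi_compliant" or "non_compliant".
#' @param nominal_pressure atm at which the balloon reaches nominal diameter.
#' @param wings folded wings (>= 2); idealized multi-wing crimped state.
#' @param membrane_thickness mm (closed-form compliance stand-in).
#' @param unfold_pressure atm below which the balloon stays folded.
#' @return object of class `balloon_spec`.
#' @export
balloon_spec <- function(nominal_diameter, length,
                         compliance_class = c("compliant", "semi_compliant",
                                              "non_compliant"),
                         nominal_pressure = 8, wings = 3L,
                         membrane_thickness = 0.03, unfold_pressure = 1) {
  compliance_class <- match.arg(compliance_class)
  stopifnot(nominal_diameter > 0, length > 0, wings >= 2L,
            nominal_pressure > unfold_pressure)
  structure(list(nominal_diameter = nominal_diameter, length = length,
                 compliance_class = compliance_class,
                 nominal_pressure = nominal_pressure, wings = as.integer(wings),
                 membrane_thickness = membrane_thickness,
                 unfold_pressure = unfold_pressure),
            class = "balloon_spec")
}

#' Balloon diameter at pressure (closed-form membrane stand-in)
#'
#' Folded diameter (nominal/4) below the unfolding threshold, linear ramp to
#' the nominal diameter at nominal pressure, then thin-walled-membrane
#' compliance growth d = d_nom (1 + (P - P_nom) d_nom / (2 t_b E_class)) with
#' the compliance-class modulus (300/900/1500 MPa). Monotone nondecreasing in
#' pressure.
#'
#' @param spec a [balloon_spec].
#' @param pressure atm (vectorized), >= 0.
#' @param table a [material_table].
#' @return diameter, mm.
#' @export
balloon_diameter_at_pressure <- function(spec, pressure,
                                         table = material_table()) {
  stopifnot(inherits(spec, "balloon_spec"))
  if (any(pressure < 0)) stop("pressure must be >= 0")
  d_nom <- spec$nominal_diameter
  d_fold <- d_nom / 4
  E <- balloon_modulus(spec$compliance_class, table)
  ifelse(pressure <= spec$unfold_pressure, d_fold,
  ifelse(pressure <= spec$nominal_pressure,
         d_fold + (d_nom - d_fold) * (pressure - spec$unfold_pressure) /
           (spec$nominal_pressure - spec$unfold_pressure),
         d_nom * (1 + atm_to_mpa(pressure - spec$nominal_pressure) * d_nom /
                    (2 * spec$membrane_thickness * E))))
}

## --- device description records (procedure tables) ------------------------

#' Stent device description for procedure tables
#'
#' @param preset stent preset name (see [stent_preset]).
#' @param diameter_mm,length_mm nominal size.
#' @param pressure_atm deployment pressure of the stent balloon.
#' @return device record (list) with `kind = "stent"`.
#' @export
stent_device <- function(preset = "integrity_like", diameter_mm = 3.0,
                         length_mm = 18, pressure_atm = 12) {
  list(kind = "stent", preset = preset, diameter_mm = diameter_mm,
       length_mm = length_mm, compliance_class = "semi_compliant",
       pressure_atm = pressure_atm)
}

#' Balloon device description for procedure tables
#'
#' @param compliance_class balloon class.
#' @param diameter_mm,length_mm size.
#' @param pressure_atm inflation pressure.
#' @return device record (list) with `kind = "balloon"`.
#' @export
balloon_device <- function(compliance_class = "non_compliant",
                           diameter_mm = 3.5, length_mm = 8,
                           pressure_atm = 18) {
  list(kind = "balloon", preset = NULL, diameter_mm = diameter_mm,
       length_mm = length_mm,
       compliance_class = match.arg(compliance_class,
                                    c("compliant", "semi_compliant",
                                      "non_compliant")),
       pressure_atm = pressure_atm)
}

## Balloon spec from a device record. Stent-delivery balloons are
## semi-compliant with nominal pressure at the labeled deployment pressure's
## scale; plain balloons reach nominal at their class-typical pressure.
device_balloon <- function(device) {
  nomP <- if (identical(device$kind, "stent")) 9 else
    switch(device$compliance_class, compliant = 5, semi_compliant = 6,
           non_compliant = 8)
  balloon_spec(device$diameter_mm, device$length_mm,
               compliance_class = device$compliance_class,
               nominal_pressure = nomP)
}

#' Export a stent geometry as CSV edge list
#'
#' @param geometry a `stent_geometry`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stent_csv <- function(geometry, path) {
  e <- geometry$edges
  df <- data.frame(
    x1 = geometry$nodes[e[, 1L], 1L], y1 = geometry$nodes[e[, 1L], 2L],
    z1 = geometry$nodes[e[, 1L], 3L], x2 = geometry$nodes[e[, 2L], 1L],
    y2 = geometry$nodes[e[, 2L], 2L], z2 = geometry$nodes[e[, 2L], 3L],
    type = geometry$edge_type)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
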