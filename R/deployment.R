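#' @title Slice-wise quasi-static deployment surrogate
#' @description Replays multi-step stenting procedures (stenting, POT,
#'   side-branch strut opening, kissing balloon inflation, pre/post
#'   dilatation) through a per-slice equilibrium between balloon pressure, an
#'   elastoplastic stent ring and the hyperelastic wall. This is a reduced
#'   surrogate for full 3D explicit finite-element contact mechanics: it
#'   preserves the procedure grammar, the constitutive laws and the
#'   qualitative contracts (pressure monotonicity, recoil, plastic set,
#'   two-layer overlap) but has no strut-level contact. Provenance constants
#'   of the reference FE setup (friction 0.2, 0.05 s inflations, 5e-8 s
#'   increments) are carried as metadata only.
#' @name deployment
NULL

#' Deployment surrogate configuration
#'
#' @param slice_spacing mm between mechanical slices (default 0.25, mirroring
#'   the reference hexahedral element size; halving 0.50 to 0.25 changes the
#'   final diameter profile by < 1 percent).
#' @param ring_k dimensionless ring-stiffness multiplier of the surrogate,
#'   calibrated so a crimped ring yields under a few atmospheres of balloon
#'   pressure (see the methods vignette).
#' @param jail_coverage fraction of the ostium cell area covered by jailing
#'   struts (effective-ostium bookkeeping).
#' @param crimp_diameter mm, diameter stents are crimped to before delivery.
#' @param tol mm, bisection tolerance of the equilibrium solver.
#' @param friction_coefficient recorded provenance value (unused by the
#'   surrogate).
#' @return list of class `deployment_config`.
#' @export
deployment_config <- function(slice_spacing = 0.25, ring_k = 0.25,
                              crimp_diameter = 1.2, tol = 1e-6,
                              jail_coverage = 0.25,
                              friction_coefficient = 0.2) {
  stopifnot(slice_spacing > 0)
  structure(list(slice_spacing = slice_spacing, ring_k = ring_k,
                 crimp_diameter = crimp_diameter, tol = tol,
                 jail_coverage = jail_coverage,
                 provenance = list(friction_coefficient = friction_coefficient,
                                   inflation_time_s = 0.05,
                                   target_increment_s = 5e-8,
                                   note = "recorded-not-simulated")),
            class = "deployment_config")
}

#' Initial deployment state from a synthetic anatomy
#'
#' Discretizes both branches into slices carrying reference lumen radius,
#' wall thickness and plaque score (NA on bench-silicone anatomies, where the
#' wall law is Neo-Hookean silicone).
#'
#' @param anatomy a `bifurcation_anatomy`.
#' @param config a [deployment_config].
#' @param table a [material_table].
#' @return object of class `deployment_state`.
#' @export
deployment_state <- function(anatomy, config = deployment_config(),
                             table = material_table()) {
  mk_branch <- function(branch) {
    b <- anat_branch(anatomy, branch)
    s <- seq(min(b$s), max(b$s), by = config$slice_spacing)
    r0 <- stats::approx(b$s, b$radius, xout = s)$y
    data.frame(arclength = s, r0 = r0, r = r0,
               thickness = stats::approx(b$s, b$wall, xout = s)$y,
               score = plaque_score_at(anatomy, branch, s),
               jailed = FALSE)
  }
  mv <- mk_branch("MV"); sb <- mk_branch("SB")
  structure(list(mv = list(slices = mv, layers = rep(list(list()), nrow(mv))),
                 sb = list(slices = sb, layers = rep(list(list()), nrow(sb))),
                 material = anatomy$material,
                 carina_arclength = anatomy$carina$arclength,
                 centerlines = list(MV = anatomy_centerline(anatomy, "MV"),
                                    SB = anatomy_centerline(anatomy, "SB")),
                 stents = list(), history = list(),
                 log = list(), config = config, table = table),
            class = "deployment_state")
}

#' @export
print.deployment_state <- function(x, ...) {
  cat("Deployment state:", nrow(x$mv$slices), "MV +", nrow(x$sb$slices),
      "SB slices,", length(x$stents), "stent(s),",
      length(x$history), "step snapshot(s)\n")
  invisible(x)
}

## Wall stress law for one slice (tissue score or silicone).
slice_stress <- function(state, score, stretch) {
  if (state$material == "silicone")
    uniaxial_stress(state$table$soft$silicone, stretch)
  else if (is.na(score))
    uniaxial_stress(state$table$soft$normal_wall, stretch)
  else stress_for_score(score, stretch, state$table)
}

#' Wall pressure of a slice at lumen radius r
#'
#' Thin-walled relation p = (t/r) sigma_theta(r/r0), with the hoop stress
#' from the slice's constitutive law (plaque score, normal wall or bench
#' silicone). Zero at the reference radius, negative in compression.
#'
#' @param state a `deployment_state`.
#' @param branch "MV" or "SB".
#' @param slice_index slice row.
#' @param r lumen radius, mm (vectorized).
#' @return pressure, MPa.
#' @export
wall_pressure <- function(state, branch, slice_index, r) {
  sl <- anat_branch(state, branch)$slices[slice_index, ]
  if (any(r < 0.5 * sl$r0)) stop("r below half the reference radius")
  (sl$thickness / r) * slice_stress(state, sl$score, r / sl$r0)
}

#' Resisting pressure of one stent ring layer at radius r
#'
#' Hoop elastoplastic ring surrogate: strain (r - r_set)/r_set through the
#' alloy's bilinear law, converted to pressure by the thin-ring relation
#' p = ring_k * sigma * A_strut / (r * w_ring). Zero at the plastic-set
#' radius; negative (outward push) when compressed below it; the elastic
#' slope is proportional to E * A (doubling the strut section doubles it).
#'
#' @param layer stent layer record (as stored on a stented slice).
#' @param r radius, mm.
#' @param ring_k stiffness multiplier.
#' @return pressure, MPa.
#' @export
ring_pressure <- function(layer, r, ring_k = 1.0) {
  eps <- (r - layer$r_set) / layer$r_set
  ring_k * alloy_stress(layer$alloy, eps) * layer$area / (r * layer$w)
}

## Sum of layer pressures at radius r; `contact` restricts to given layers.
layers_pressure <- function(layers, r, ring_k, contact = seq_along(layers)) {
  if (length(contact) == 0L) return(0)
  sum(vapply(layers[contact], ring_pressure, numeric(1L), r = r,
             ring_k = ring_k))
}

## Deterministic bisection for increasing f with f(lo) <= 0.
bisect <- function(f, lo, hi, tol) {
  flo <- f(lo)
  if (flo > 0) return(lo)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

## Slice indices of a branch inside an arclength window [w1, w2].
window_slices <- function(state, branch, window) {
  s <- anat_branch(state, branch)$slices$arclength
  which(s >= window[1L] - 1e-9 & s <= window[2L] + 1e-9)
}

#' Inflate a balloon over an arclength window
#'
#' Per slice, the new lumen radius solves
#' P = wall_pressure(r) + sum of ring pressures, clamped above by the balloon
#' radius at that pressure (bisection to the configured tolerance). Slices
#' outside the window are untouched; zero pressure is the identity.
#'
#' @param state a `deployment_state`.
#' @param balloon a [balloon_spec].
#' @param pressure_atm inflation pressure.
#' @param window list(branch =, range = c(start, end) mm); SB arclength is
#'   measured from the carina.
#' @param r_clamp optional override of the clamp radius (used by KBI for the
#'   combined balloon cross-section).
#' @return updated state.
#' @export
inflate <- function(state, balloon, pressure_atm, window, r_clamp = NULL) {
  if (pressure_atm < 0) stop("pressure must be >= 0")
  if (pressure_atm == 0) return(state)
  P <- atm_to_mpa(pressure_atm)
  r_b <- if (is.null(r_clamp))
    balloon_diameter_at_pressure(balloon, pressure_atm, state$table) / 2
  else r_clamp
  br <- tolower(window$branch)
  idx <- window_slices(state, window$branch, window$range)
  cfg <- state$config
  for (i in idx) {
    sl <- state[[br]]$slices[i, ]
    layers <- state[[br]]$layers[[i]]
    f <- function(r)
      wall_pressure(state, window$branch, i, r) +
        layers_pressure(layers, r, cfg$ring_k) - P
    hi <- max(r_b, sl$r, sl$r0)
    r_eq <- min(bisect(f, 0.5 * sl$r0 + 1e-9, hi, cfg$tol), r_b)
    if (r_eq > sl$r) state[[br]]$slices$r[i] <- r_eq
    ## stent layers ride the balloon out to min(clamp, wall)
    push <- min(r_b, max(r_eq, sl$r))
    for (k in seq_along(layers)) {
      state[[br]]$layers[[i]][[k]]$r_peak <-
        max(layers[[k]]$r_peak, min(push, state[[br]]$slices$r[i]))
    }
  }
  state
}

#' Balloon deflation with elastic recoil
#'
#' Plastic set of each loaded stent layer is updated from its peak strain
#' (elastic unloading at slope E), then each slice settles where the wall
#' pressure balances the stent rings at their new set radii. Unstented
#' slices return exactly to the reference radius; stented slices loaded past
#' yield retain a residual gain. Recoil never increases a radius.
#'
#' @param state a `deployment_state`.
#' @param window list(branch =, range =).
#' @return updated state.
#' @export
deflate_recoil <- function(state, window) {
  br <- tolower(window$branch)
  idx <- window_slices(state, window$branch, window$range)
  cfg <- state$config
  for (i in idx) {
    layers <- state[[br]]$layers[[i]]
    ## plastic update from the loading peak
    for (k in seq_along(layers)) {
      ly <- layers[[k]]
      if (ly$r_peak > ly$r_set) {
        epk <- (ly$r_peak - ly$r_set) / ly$r_set
        spk <- alloy_stress(ly$alloy, epk)
        E <- ly$alloy$elastic_modulus * 1000
        if (epk > ly$alloy$yield_strength / E) {
          ly$r_set <- ly$r_peak / (1 + spk / E)
        }
      }
      ly$r_peak <- ly$r_set
      layers[[k]] <- ly
    }
    sl <- state[[br]]$slices[i, ]
    if (length(layers) == 0L) {
      r_new <- sl$r0
    } else {
      sets <- vapply(layers, function(l) l$r_set, numeric(1L))
      contact <- which(sets > sl$r0)
      repeat {
        if (length(contact) == 0L) { r_new <- sl$r0; break }
        g <- function(r)
          wall_pressure(state, window$branch, i, r) +
            layers_pressure(layers, r, cfg$ring_k, contact)
        r_new <- bisect(g, 0.5 * sl$r0 + 1e-9,
                        max(sl$r0, max(sets[contact])), cfg$tol)
        still <- contact[sets[contact] >= r_new - cfg$tol]
        if (length(still) == length(contact)) break
        contact <- still
      }
    }
    state[[br]]$slices$r[i] <- min(sl$r, max(r_new, 0.5 * sl$r0))
    state[[br]]$layers[[i]] <- layers
  }
  state
}

## Effective alloy for a (possibly shell-core) strut: shell law with
## area-weighted modulus.
stent_layer_alloy <- function(design, table) {
  a <- table$alloys[[design$alloy]]
  a$elastic_modulus <- effective_strut_modulus(design, table) / 1000
  a
}

## Register a stent layer on the covered slices of one branch.
add_stent_layer <- function(state, branch, idx, stent_id, design, r_crimp) {
  br <- tolower(branch)
  alloy <- stent_layer_alloy(design, state$table)
  w <- design$nominal_length / design$rings
  for (i in idx) {
    if (length(state[[br]]$layers[[i]]) >= 2L)
      stop("more than two stent layers on one slice")
    state[[br]]$layers[[i]][[length(state[[br]]$layers[[i]]) + 1L]] <-
      list(stent_id = stent_id, r_set = r_crimp, r_peak = r_crimp,
           alloy = alloy, area = strut_area(design),
           w = w, thickness = strut_thickness(design))
  }
  state
}

#' Deploy a stent (crimped registration + inflation + recoil)
#'
#' The crimped stent is registered to the slices of its placement window, a
#' layer added per covered slice, then the delivery balloon is inflated at
#' the given pressure and deflated with recoil. An MV stent whose window
#' crosses the carina jails the SB ostium slices.
#'
#' @param state a `deployment_state`.
#' @param device a [stent_device] record.
#' @param pressure_atm deployment pressure.
#' @param window list(mv = c(start, end) or NULL, sb = c(start, end) or
#'   NULL): arclength windows covered on each branch (culotte/TAP protrusion
#'   covers both).
#' @return updated state.
#' @export
deploy_stent <- function(state, device, pressure_atm, window) {
  stopifnot(identical(device$kind, "stent"))
  design <- stent_preset(device$preset, device$diameter_mm, device$length_mm)
  stent_id <- length(state$stents) + 1L
  r_crimp <- state$config$crimp_diameter / 2
  idx_mv <- if (!is.null(window$mv)) window_slices(state, "MV", window$mv)
            else integer()
  idx_sb <- if (!is.null(window$sb)) window_slices(state, "SB", window$sb)
            else integer()
  if (length(idx_mv)) state <- add_stent_layer(state, "MV", idx_mv, stent_id,
                                               design, r_crimp)
  if (length(idx_sb)) state <- add_stent_layer(state, "SB", idx_sb, stent_id,
                                               design, r_crimp)
  balloon <- device_balloon(device)
  for (w in list(list(branch = "MV", range = window$mv),
                 list(branch = "SB", range = window$sb))) {
    if (is.null(w$range)) next
    state <- inflate(state, balloon, pressure_atm, w)
    state <- deflate_recoil(state, w)
  }
  ## jailing: MV stent crossing the carina covers the SB ostium
  if (!is.null(window$mv) &&
      window$mv[1L] < state$carina_arclength &&
      window$mv[2L] > state$carina_arclength) {
    d_ost <- 2 * state$sb$slices$r0[1L]
    state$sb$slices$jailed[state$sb$slices$arclength <= d_ost] <- TRUE
  }
  state$stents[[stent_id]] <- list(id = stent_id, design = design,
                                   device = device, window = window,
                                   r_crimp = r_crimp)
  state
}

#' Proximal optimization technique (POT)
#'
#' Inflation plus recoil confined to a proximal MV window ending at or
#' before the carina.
#'
#' @param state a `deployment_state`.
#' @param device a [balloon_device] record.
#' @param pressure_atm atm.
#' @param window c(start, end), clipped at the carina.
#' @return updated state.
#' @export
pot <- function(state, device, pressure_atm, window = NULL) {
  if (is.null(window))
    window <- c(state$carina_arclength - device$length_mm,
                state$carina_arclength)
  window[2L] <- min(window[2L], state$carina_arclength)
  w <- list(branch = "MV", range = window)
  state <- inflate(state, device_balloon(device), pressure_atm, w)
  deflate_recoil(state, w)
}

#' Side-branch strut opening
#'
#' Inflates the ostium-adjacent SB slices, clearing the jailed marker on the
#' (distal-cell) recross aperture; the effective ostium area increases.
#'
#' @param state a `deployment_state`.
#' @param device a [balloon_device] record.
#' @param pressure_atm atm.
#' @param window SB arclength window (default ostium to the balloon length).
#' @return updated state.
#' @export
sb_open <- function(state, device, pressure_atm, window = NULL) {
  if (is.null(window)) window <- c(0, device$length_mm)
  w <- list(branch = "SB", range = window)
  state <- inflate(state, device_balloon(device), pressure_atm, w)
  state <- deflate_recoil(state, w)
  idx <- window_slices(state, "SB", window)
  state$sb$slices$jailed[idx] <- FALSE
  state$recross_cell <- "distal"
  state
}

#' Kissing balloon inflation (KBI)
#'
#' Overlap slices of the proximal MV see the combined cross-section of the
#' two balloons (area sum, area-equivalent radius) as the clamp; non-overlap
#' slices behave as single-balloon inflations on their branch.
#'
#' @param state a `deployment_state`.
#' @param device_mv,device_sb balloon (or stent-balloon) device records.
#' @param pressure_mv_atm,pressure_sb_atm atm.
#' @param overlap_mm length of the proximal-MV overlap zone.
#' @return updated state.
#' @export
kbi <- function(state, device_mv, device_sb, pressure_mv_atm,
                pressure_sb_atm, overlap_mm = 3) {
  car <- state$carina_arclength
  b_mv <- device_balloon(device_mv)
  b_sb <- device_balloon(device_sb)
  r1 <- balloon_diameter_at_pressure(b_mv, pressure_mv_atm, state$table) / 2
  r2 <- balloon_diameter_at_pressure(b_sb, pressure_sb_atm, state$table) / 2
  r_comb <- sqrt(r1^2 + r2^2)
  w_over <- list(branch = "MV", range = c(car - overlap_mm, car))
  w_prox <- list(branch = "MV",
                 range = c(car - device_mv$length_mm, car - overlap_mm))
  w_sb <- list(branch = "SB", range = c(0, device_sb$length_mm))
  state <- inflate(state, b_mv, pressure_mv_atm, w_over, r_clamp = r_comb)
  state <- inflate(state, b_mv, pressure_mv_atm, w_prox)
  state <- inflate(state, b_sb, pressure_sb_atm, w_sb)
  for (w in list(w_over, w_prox, w_sb)) state <- deflate_recoil(state, w)
  state
}

#' Per-slice strut malapposition gaps
#'
#' Gap = max(0, lumen radius - stent ring radius - strut thickness) per
#' stented slice; an apposed layer rides the wall and has zero gap.
#'
#' @param state a `deployment_state`.
#' @return data.frame: branch, arclength, stent_id, gap_mm.
#' @export
malapposition_map <- function(state) {
  out <- list()
  for (br in c("mv", "sb")) {
    sl <- state[[br]]$slices
    for (i in seq_len(nrow(sl))) {
      for (ly in state[[br]]$layers[[i]]) {
        r_layer <- min(sl$r[i], ly$r_set)
        out[[length(out) + 1L]] <- data.frame(
          branch = toupper(br), arclength = sl$arclength[i],
          stent_id = ly$stent_id,
          gap_mm = max(0, sl$r[i] - r_layer - ly$thickness))
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(branch = character(), arclength = numeric(),
                      stent_id = integer(), gap_mm = numeric()))
  do.call(rbind, out)
}

## Resolve a procedure step's placement to explicit windows.
resolve_window <- function(state, st, resolved) {
  car <- state$carina_arclength
  L <- st$device$length_mm
  pl <- st$placement
  if (!is.null(pl) && identical(pl$mode, "relative_to_step")) {
    ref <- resolved[[pl$reference_step]]
    off <- if (is.null(pl$value_mm) || pl$value_mm == 0) L / 2 else pl$value_mm
    rng <- ref$primary - off
    return(list(mv = rng, sb = NULL, primary = rng))
  }
  switch(st$action,
    stent = {
      if (st$branch == "MV") {
        rng <- c(car - 0.6 * L, car + 0.4 * L)
        rng <- pmax(pmin(rng, max(state$mv$slices$arclength)), 0)
        list(mv = rng, sb = NULL, primary = rng)
      } else {
        prot <- if (!is.null(pl) && identical(pl$mode, "protrusion"))
          pl$value_mm else 0
        list(mv = if (prot > 0) c(car - prot, car) else NULL,
             sb = c(0, min(L - prot, max(state$sb$slices$arclength))),
             primary = c(0, L - prot))
      }
    },
    pot = { rng <- c(car - L, car); list(mv = rng, sb = NULL, primary = rng) },
    sb_open = { rng <- c(0, min(L, 3)); list(sb = rng, mv = NULL,
                                             primary = rng) },
    kbi = { rng <- c(car - L, car); list(mv = rng, sb = NULL, primary = rng) },
    predilate = ,
    postdilate = {
      if (st$branch == "MV") {
        rng <- c(car - 0.6 * L, car + 0.4 * L)
        rng <- pmax(pmin(rng, max(state$mv$slices$arclength)), 0)
        list(mv = rng, sb = NULL, primary = rng)
      } else list(sb = c(0, L), mv = NULL, primary = c(0, L))
    })
}

#' Run a multi-step procedure
#'
#' Applies the steps of a [generate_procedure] table in order; the stressed
#' state after each step is the initial condition of the next, and a
#' snapshot of every intermediate state is kept. Deterministic. A
#' balloon-only step before any stent has been deployed raises an ordering
#' warning.
#'
#' @param state initial `deployment_state`.
#' @param table a `procedure_table`.
#' @return final state; per-step snapshots in `$history`, an auditable log
#'   (device, pressures in atm and MPa, window) in `$log`.
#' @export
run_procedure <- function(state, table) {
  stopifnot(inherits(table, "procedure_table"))
  resolved <- list()
  for (st in table$steps) {
    if (st$action %in% c("pot", "sb_open", "kbi") &&
        length(state$stents) == 0L)
      warning(sprintf("step #%d (%s) references a stent before any was deployed",
                      st$step, st$action))
    win <- resolve_window(state, st, resolved)
    resolved[[st$step]] <- win
    state <- switch(st$action,
      stent = deploy_stent(state, st$device, st$pressure_atm,
                           list(mv = win$mv, sb = win$sb)),
      pot = pot(state, st$device, st$pressure_atm, win$mv),
      sb_open = sb_open(state, st$device, st$pressure_atm, win$sb),
      kbi = kbi(state, st$device, st$device_sb, st$pressure_atm,
                st$device_sb$pressure_atm),
      predilate = ,
      postdilate = {
        w <- if (!is.null(win$mv)) list(branch = "MV", range = win$mv)
             else list(branch = "SB", range = win$sb)
        s2 <- inflate(state, device_balloon(st$device), st$pressure_atm, w)
        deflate_recoil(s2, w)
      })
    state$log[[length(state$log) + 1L]] <- list(
      step = st$step, action = st$action, branch = st$branch,
      device = device_label(st$device), pressure_atm = st$pressure_atm,
      pressure_MPa = atm_to_mpa(st$pressure_atm),
      window = win[c("mv", "sb")],
      provenance = state$config$provenance)
    snap <- state
    snap$history <- NULL
    state$history[[length(state$history) + 1L]] <- snap
  }
  state
}

#' Effective SB ostium area of a deployment state
#'
#' Area-equivalent bookkeeping over the ostium-adjacent SB slices (one
#' reference diameter from the carina): pi r^2 per slice, reduced by the
#' configured strut coverage fraction while the slice is jailed by an MV
#' stent. Side-branch strut opening clears the jailed marker (recross through
#' the distal cell), so the effective area strictly increases.
#'
#' @param state a `deployment_state`.
#' @return mm^2.
#' @export
ostium_area <- function(state) {
  d0 <- 2 * state$sb$slices$r0[1L]
  idx <- which(state$sb$slices$arclength <= d0)
  cover <- ifelse(state$sb$slices$jailed[idx], state$config$jail_coverage, 0)
  mean(pi * state$sb$slices$r[idx]^2 * (1 - cover))
}

#' 3D geometry of a deployed stent
#'
#' Rebuilds the stent strut graph in 3D from the deployment state: the
#' nominal pattern is bent along the branch centerline over its placement
#' window and each node placed at the local stent ring radius (layer radius
#' minus half a strut thickness, the strut centerline).
#'
#' @param state a `deployment_state` after [run_procedure]/[deploy_stent].
#' @param stent_id index into `state$stents`.
#' @return a `stent_geometry` with state tag "deployed".
#' @export
deployed_stent_geometry <- function(state, stent_id = 1L) {
  rec <- state$stents[[stent_id]]
  design <- rec$design
  geom <- build_nominal_stent(design)
  branch <- if (!is.null(rec$window$mv) &&
                (is.null(rec$window$sb) ||
                 diff(rec$window$mv) >= diff(rec$window$sb))) "MV" else "SB"
  win <- if (branch == "MV") rec$window$mv else rec$window$sb
  cl <- state$centerlines[[branch]]
  sl <- anat_branch(state, branch)$slices
  ## layer (strut-centerline) radius per arclength for this stent
  r_layer <- vapply(seq_len(nrow(sl)), function(i) {
    for (ly in anat_branch(state, branch)$layers[[i]])
      if (ly$stent_id == stent_id)
        return(min(sl$r[i], ly$r_set) - ly$thickness / 2)
    NA_real_
  }, numeric(1L))
  ok <- !is.na(r_layer)
  zmin <- min(geom$nodes[, 1L])
  zspan <- max(geom$nodes[, 1L]) - zmin
  start <- max(win[1L], min(cl$s))
  scale <- min(1, (min(win[2L], max(cl$s)) - start) / zspan)
  s_node <- start + (geom$nodes[, 1L] - zmin) * scale
  r_node <- stats::approx(sl$arclength[ok], r_layer[ok], xout = s_node,
                          rule = 2)$y
  th <- atan2(geom$nodes[, 3L], geom$nodes[, 2L])
  s_f <- sort(unique(c(cl$s, s_node)))
  s_f <- s_f[c(TRUE, diff(s_f) > 1e-9)]
  cl_f <- resample_polyline(cl$points, cl$s, s_f)
  fr <- rm_frames(cl_f)
  idx <- vapply(s_node, function(v) which.min(abs(s_f - v)), integer(1L))
  geom$nodes <- cl_f[idx, , drop = FALSE] +
    r_node * cos(th) * fr$n1[idx, , drop = FALSE] +
    r_node * sin(th) * fr$n2[idx, , drop = FALSE]
  geom$state <- "deployed"
  geom$arclength <- s_node
  geom$branch <- branch
  geom
}

#' Export deployment slices as CSV
#'
#' Columns: branch, arclength, r (mm), layer count, malapposition gap.
#'
#' @param state a `deployment_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deployment_csv <- function(state, path) {
  rows <- list()
  for (br in c("mv", "sb")) {
    sl <- state[[br]]$slices
    nl <- vapply(state[[br]]$layers, length, integer(1L))
    rows[[br]] <- data.frame(branch = toupper(br), arclength = sl$arclength,
                             r_mm = sl$r, layers = nl, jailed = sl$jailed)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
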