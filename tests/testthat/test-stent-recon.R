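# Stent reconstruction from strut detections: unroll, register, wrap, sweep.

# deployed, well-apposed stent + centerline fixture (straight vessel); the
# wrap places struts on the lumen surface, so apposition makes the round
# trip exact up to detection quantization
recon_fixture <- function(seed = 1) {
  st <- fix_state(plain_params())
  stn <- deploy_stent(st, stent_device("integrity_like", 3.5, 18, 16), 16,
                      list(mv = c(6, 24), sb = NULL))
  truth <- deployed_stent_geometry(stn, 1L)
  list(state = stn, truth = truth, cl = stn$centerlines$MV)
}

test_that("unroll maps angles to arc coordinates and inverts", {
  fx <- recon_fixture()
  cloud <- simulate_strut_detections(fx$truth, fx$cl, 0.2)
  u <- unroll(cloud)
  # single point at theta = 0 has arc coordinate 0
  expect_equal(u$points$arc_mm[cloud$points$angle_deg < 1e-9][1L], 0)
  # inverse: arc / r back to angles
  ang_back <- (u$points$arc_mm / u$frame_radius[u$points$frame]) * 180 / pi
  expect_lt(max(abs(ang_back - cloud$points$angle_deg)), 1e-9)
  expect_equal(u$period, 2 * pi * u$frame_radius)
})

test_that("points on a helix unroll to a line", {
  # analytic helix on a cylinder of radius 1.4: theta = c * z
  z <- seq(0, 10, by = 0.2)
  theta <- (36 * z) %% 360
  cloud <- structure(list(points = data.frame(frame = seq_along(z),
                                              angle_deg = theta,
                                              radius_mm = 1.4),
                          frame_s = z, frame_spacing = 0.2),
                     class = "strut_cloud")
  u <- unroll(cloud, frame_radius = rep(1.4, length(z)))
  arc_unwrapped <- (36 * z) * pi / 180 * 1.4     # before wrapping
  k <- arc_unwrapped - u$points$arc_mm
  expect_lt(max(abs(k / (2 * pi * 1.4) - round(k / (2 * pi * 1.4)))), 1e-9)
  fit <- stats::lm(arc_unwrapped ~ u$points$z_mm)
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)   # collinear
})

test_that("registration of exact pattern samples is a perfect match", {
  fx <- recon_fixture()
  cloud <- simulate_strut_detections(fx$truth, fx$cl, 0.2)
  m <- register_pattern(unroll(cloud), fx$truth$design)
  expect_length(m$missing_nodes, 0L)
  expect_false(m$low_confidence)
  expect_lt(m$residual_mm, 0.1)
  n_nodes <- fx$truth$design$rings * 2L * fx$truth$design$crowns_per_ring
  expect_equal(sum(!is.na(m$assignment)), n_nodes)
})

test_that("registration survives 20% known deletions and reports them", {
  fx <- recon_fixture()
  cloud <- simulate_strut_detections(fx$truth, fx$cl, 0.2)
  # known deletions: drop the two distal rings (~20% of the points); the
  # remaining subgraph stays connected by construction
  n_nodes <- fx$truth$design$rings * 2L * fx$truth$design$crowns_per_ring
  thr <- stats::quantile(cloud$frame_s[cloud$points$frame], 0.8)
  keep <- which(cloud$frame_s[cloud$points$frame] <= thr)
  cloud$points <- cloud$points[keep, ]
  m <- register_pattern(unroll(cloud), fx$truth$design)
  expect_equal(length(m$missing_nodes), n_nodes - length(keep))
  # matched subgraph is still connected
  sub <- list(nodes = matrix(0, nrow = length(unique(stats::na.omit(
    m$assignment))), ncol = 3L),
    edges = matrix(match(m$edges, sort(unique(stats::na.omit(m$assignment)))),
                   ncol = 2L))
  sub$edges <- sub$edges[stats::complete.cases(sub$edges), , drop = FALSE]
  expect_true(stent_graph_connected(sub))
})

test_that("registration is equivariant under circumferential rotation", {
  # the zig-zag pattern repeats every 2 angular bins (45 degrees here), so
  # rotation is recoverable modulo that symmetry; use a 30-degree rotation
  fx <- recon_fixture()
  cloud <- simulate_strut_detections(fx$truth, fx$cl, 0.2)
  m0 <- register_pattern(unroll(cloud), fx$truth$design)
  rot <- cloud
  rot$points$angle_deg <- (rot$points$angle_deg + 30) %% 360
  m30 <- register_pattern(unroll(rot), fx$truth$design)
  bin <- 360 / (2 * fx$truth$design$crowns_per_ring)
  sym <- 2 * bin
  delta <- (m30$rotation_deg - m0$rotation_deg) %% sym
  expect_lt(min(abs(delta - 30 %% sym), abs(delta - 30 %% sym + sym),
                abs(delta - 30 %% sym - sym)), bin + 1e-6)
})

test_that("full round trip: deployment -> detection -> reconstruction", {
  fx <- recon_fixture()
  cloud <- simulate_strut_detections(fx$truth, fx$cl, 0.2)
  m <- register_pattern(unroll(cloud), fx$truth$design)
  sl <- fx$state$mv$slices
  rec <- wrap_to_3d(m, fx$cl, data.frame(arclength = sl$arclength, r = sl$r))
  rmse <- sqrt(mean(rowSums((rec$nodes -
                             fx$truth$nodes[rec$node_ids, , drop = FALSE])^2)))
  expect_lt(rmse, strut_thickness(fx$truth$design))
  # crown and link counts exactly equal the design
  d <- fx$truth$design
  expect_equal(sum(rec$edge_type == "crown_arm"), d$rings * 2L *
                 d$crowns_per_ring)
  expect_equal(sum(rec$edge_type == "link"),
               (d$rings - 1L) * d$links_per_ring_pair)
})

test_that("seam edges have periodic-geodesic length", {
  fx <- recon_fixture()
  cloud <- simulate_strut_detections(fx$truth, fx$cl, 0.2)
  m <- register_pattern(unroll(cloud), fx$truth$design)
  sl <- fx$state$mv$slices
  rec <- wrap_to_3d(m, fx$cl, data.frame(arclength = sl$arclength, r = sl$r))
  # edges crossing theta = 0: angular difference must be measured mod 360
  a1 <- rec$angle_deg[rec$edges[, 1L]]
  a2 <- rec$angle_deg[rec$edges[, 2L]]
  dang <- pmin(abs(a1 - a2), 360 - abs(a1 - a2))
  lens <- sqrt(rowSums((rec$nodes[rec$edges[, 1L], , drop = FALSE] -
                        rec$nodes[rec$edges[, 2L], , drop = FALSE])^2))
  crossing <- abs(a1 - a2) > 180
  expect_true(any(crossing))
  r_mean <- mean(sqrt(rec$nodes[, 2L]^2 + rec$nodes[, 3L]^2))
  chord <- 2 * r_mean * sin(dang[crossing] * pi / 360)
  expect_true(all(lens[crossing] <= sqrt(chord^2 + 4) + 1e-6))
})

test_that("strut volume sweep: tube area, watertight, zero-length warning", {
  g <- structure(list(
    nodes = rbind(c(0, 0, 0), c(10, 0, 0)),
    edges = matrix(c(1L, 2L), 1L),
    edge_type = "crown_arm",
    design = stent_design(strut_section = list(shape = "circular",
                                               diameter_mm = 0.2))),
    class = "stent_geometry")
  mesh <- add_strut_volume(g, n_side = 24L)
  lateral <- pi * 0.2 * 10
  caps <- 2 * pi * 0.1^2
  expect_lt(abs(mesh_area(mesh) - (lateral + caps)) / (lateral + caps), 0.02)
  expect_true(mesh_is_watertight(mesh))
  g2 <- g
  g2$nodes <- rbind(g$nodes, c(10, 0, 0))
  g2$edges <- rbind(g2$edges, c(2L, 3L))
  g2$edge_type <- c("crown_arm", "link")
  expect_warning(add_strut_volume(g2), "zero-length")
})
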