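# Biplane fusion, outer-border rules, alignment, lofting, merging, profiles.

test_that("biplane fusion recovers a helix to within 0.05 mm", {
  t <- seq(0, 4 * pi, length.out = 400)
  helix <- cbind(2 * t, 3 * cos(t), 3 * sin(t))
  ca <- stentsim:::project_curve(helix, rep(0, nrow(helix)), 0)
  cb <- stentsim:::project_curve(helix, rep(0, nrow(helix)), 90)
  cl <- centerline_from_biplane(ca, cb, n = 400)
  truth <- resample_polyline(helix, helix[, 1L], cl$points[, 1L])
  err <- mean(sqrt(rowSums((cl$points - truth)^2)))
  expect_lt(err, 0.05)
})

test_that("straight segment from two orthogonal views is an exact line", {
  seg <- cbind(seq(0, 20, 0.5), 1.5, -2.0)
  ca <- stentsim:::project_curve(seg, rep(0, nrow(seg)), 10)
  cb <- stentsim:::project_curve(seg, rep(0, nrow(seg)), 100)
  cl <- centerline_from_biplane(ca, cb, n = 50)
  expect_lt(max(abs(cl$points[, 2L] - 1.5)), 1e-9)
  expect_lt(max(abs(cl$points[, 3L] + 2.0)), 1e-9)
  expect_error(centerline_from_biplane(ca, ca), "30 degrees")
})

test_that("outer-border rule: interpolate below 180 degrees, discard above", {
  an <- generate_bifurcation(plain_params())
  mk <- function(arcs) {
    pb <- generate_oct_pullback(an, "MV", 1.0,
                                dropout_sampler = function(i) arcs)
    pb$frames[[5L]]
  }
  done <- complete_outer_contour(mk(c(10, 100)))       # 90 degrees
  expect_false(attr(done, "discard"))
  expect_false(anyNA(done$outer_radius))
  expect_true(attr(complete_outer_contour(mk(c(0, 200))), "discard"))
  # exactly 180: interpolable by convention
  expect_false(attr(complete_outer_contour(mk(c(0, 180))), "discard"))
  # no missing arcs: unchanged
  fr <- mk(NULL)
  out <- complete_outer_contour(fr)
  expect_equal(out$outer_radius, fr$outer_radius)
  # interpolation reproduces the true circular border on synthetic frames
  expect_lt(max(abs(done$outer_radius - mk(NULL)$outer_radius)), 1e-6)
})

test_that("discard rule is a pure function of total missing arc (property)", {
  an <- generate_bifurcation(plain_params())
  set.seed(99)
  for (k in 1:100) {
    total <- stats::runif(1, 20, 340)
    start <- stats::runif(1, 0, 360)
    fr <- generate_oct_pullback(an, "MV", 1.0, dropout_sampler =
      function(i) c(start, start + total))$frames[[3L]]
    out <- complete_outer_contour(fr)
    expect_identical(attr(out, "discard"), total > 180,
                     label = sprintf("total=%.1f", total))
  }
})

test_that("alignment places the carina frame exactly and spaces frames evenly", {
  an <- generate_bifurcation(plain_params())
  cl <- anatomy_centerline(an, "MV")
  pb <- generate_oct_pullback(an, "MV", 0.5)
  pos <- suppressWarnings(align_pullback(pb, cl))
  ci <- which(pos$frame_index == pb$carina_frame_index)
  expect_equal(pos$s[ci], an$carina$arclength)
  # ten frames more proximal sit 5.0 mm away
  cj <- which(pos$frame_index == pb$carina_frame_index + 10L)
  expect_equal(abs(pos$s[cj] - pos$s[ci]), 5.0)
  cl_nocar <- anatomy_centerline(an, "MV")
  cl_nocar$carina_arclength <- NA_real_
  expect_error(align_pullback(pb, cl_nocar), "carina")
})

test_that("aligned slice areas match the generator profile within 1%", {
  an <- generate_bifurcation(stenosed_params(slice_spacing = 0.25))
  pos <- suppressWarnings(align_pullback(
    generate_oct_pullback(an, "MV", 0.5), anatomy_centerline(an, "MV")))
  lf <- loft_branch(pos)
  prof <- slice_profile(lf, 0.5)
  truth <- pi * (branch_diameter(an, "MV", prof$arclength_mm) / 2)^2
  expect_lt(max(abs(prof$area_mm2 - truth) / truth), 0.01)
})

test_that("lofting: cylinder area, discarded-frame bridging, stenosis depth", {
  an <- generate_bifurcation(plain_params())
  cl <- anatomy_centerline(an, "MV")
  pb <- generate_oct_pullback(an, "MV", 1.0)
  lf <- loft_branch(suppressWarnings(align_pullback(pb, cl)))
  r <- 1.75; L <- max(lf$s) - min(lf$s)
  lateral <- 2 * pi * r * L
  caps <- 2 * pi * r^2
  expect_lt(abs(mesh_area(lf$inner) - (lateral + caps)) / (lateral + caps),
            0.005)
  expect_true(mesh_is_watertight(lf$inner))
  # one interior frame discarded: still watertight, no hole
  pb2 <- generate_oct_pullback(an, "MV", 1.0, dropout_sampler =
    function(i) if (i == 10L) c(0, 200) else NULL)
  pos2 <- suppressWarnings(align_pullback(pb2, cl))
  expect_equal(sum(pos2$discard$discarded), 1L)
  expect_true(mesh_is_watertight(loft_branch(pos2)$inner))
  # lofted stenosis minimum area within 2% of the generator value
  ans <- generate_bifurcation(stenosed_params(slice_spacing = 0.25))
  lfs <- loft_branch(suppressWarnings(align_pullback(
    generate_oct_pullback(ans, "MV", 0.25), anatomy_centerline(ans, "MV"))))
  prof <- slice_profile(lfs, 0.25)
  a_true <- pi * (min(branch_diameter(ans, "MV", seq(0, 30, 0.05))) / 2)^2
  expect_lt(abs(min(prof$area_mm2) - a_true) / a_true, 0.02)
  expect_error(loft_branch(structure(list(rings_lumen = list()),
                                     class = "positioned_frames")),
               "2 usable frames")
})

test_that("branch merge: watertight union, ostium ellipse, volume containment", {
  an <- generate_bifurcation(plain_params(n_angles = 48L))
  mv <- loft_branch(suppressWarnings(align_pullback(
    generate_oct_pullback(an, "MV", 0.5), anatomy_centerline(an, "MV"))))
  sb <- loft_branch(suppressWarnings(align_pullback(
    generate_oct_pullback(an, "SB", 0.5), anatomy_centerline(an, "SB"))))
  bg <- merge_branches(mv, sb, h = 0.45)
  expect_true(mesh_is_watertight(bg$lumen))
  expect_true(mesh_is_watertight(bg$wall))
  expect_gte(bg$volume_mm3, max(bg$branch_volumes_mm3))
  # SB ostium ~ ellipse: pi (d/2)^2 / sin(angle) for an oblique cut
  ang <- an$params$bifurcation_angle * pi / 180
  oracle <- pi * (an$params$sb_diameter / 2)^2 / abs(sin(ang))
  expect_lt(abs(bg$ostium$area_mm2 - oracle) / oracle, 0.10)
  # non-intersecting branches are rejected
  sb_far <- sb
  for (i in seq_along(sb_far$rings_lumen))
    sb_far$rings_lumen[[i]][, 2L] <- sb_far$rings_lumen[[i]][, 2L] + 50
  sb_far$centerline$points[, 2L] <- sb_far$centerline$points[, 2L] + 50
  expect_error(merge_branches(mv, sb_far, h = 0.45), "intersect")
})

test_that("slice profiles: cylinder, stenosis dip, refinement stability", {
  an <- generate_bifurcation(anatomy_params(proximal_mv_diameter = 3.0,
                                            distal_mv_diameter = 3.0,
                                            taper_rate = 0,
                                            slice_spacing = 0.5))
  lf <- loft_branch(suppressWarnings(align_pullback(
    generate_oct_pullback(an, "MV", 0.5), anatomy_centerline(an, "MV"))))
  prof <- slice_profile(lf, 0.5)
  expect_equal(prof$diameter_mm, rep(prof$diameter_mm[1L], nrow(prof)),
               tolerance = 1e-9)
  expect_equal(prof$diameter_mm[1L], 3.0, tolerance = 0.002)
  # 60% stenosis dips to 40% of the local reference
  ans <- generate_bifurcation(stenosed_params(slice_spacing = 0.25))
  lfs <- loft_branch(suppressWarnings(align_pullback(
    generate_oct_pullback(ans, "MV", 0.25), anatomy_centerline(ans, "MV"))))
  ps <- slice_profile(lfs, 0.25)
  ref_at_min <- (3.5 - ans$params$taper_rate * 10)
  expect_equal(min(ps$diameter_mm) / ref_at_min, 0.4, tolerance = 0.01)
  # halving the sampling changes the profile only by interpolation error
  p1 <- slice_profile(lfs, 0.5)
  p2 <- slice_profile(lfs, 0.25)
  common <- intersect(p1$arclength_mm, p2$arclength_mm)
  expect_equal(p1$diameter_mm[match(common, p1$arclength_mm)],
               p2$diameter_mm[match(common, p2$arclength_mm)],
               tolerance = 1e-9)
  expect_error(slice_profile(lfs, 0), "spacing")
})
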