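# Synthetic anatomy, pullback, projection, bench variant, procedure tables.

test_that("diameter profile is taper times stenosis factor", {
  an <- generate_bifurcation(plain_params())
  expect_equal(branch_diameter(an, "MV", seq(0, 30, 1)), rep(3.5, 31))
  p2 <- anatomy_params(proximal_mv_diameter = 3.0, distal_mv_diameter = 3.0,
                       taper_rate = 0, slice_spacing = 0.25,
                       stenoses = data.frame(branch = "MV", center_mm = 10,
                                             severity = 0.6, length_mm = 8))
  an2 <- generate_bifurcation(p2)
  expect_equal(min(branch_diameter(an2, "MV", seq(0, 30, 0.25))), 1.2)
})

test_that("generation is deterministic for fixed params and seed", {
  a <- generate_bifurcation(stenosed_params())
  b <- generate_bifurcation(stenosed_params())
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  pa <- generate_oct_pullback(a, "MV", 0.5, seed = 11)
  pb <- generate_oct_pullback(b, "MV", 0.5, seed = 11)
  expect_identical(serialize(pa, NULL), serialize(pb, NULL))
})

test_that("stenoses overlapping the carina are rejected", {
  p <- anatomy_params(stenoses = data.frame(branch = "MV", center_mm = 18,
                                            severity = 0.4, length_mm = 6))
  expect_error(generate_bifurcation(p), "carina")
  expect_error(anatomy_params(stenoses = data.frame(branch = "MV",
                                                    center_mm = 10,
                                                    severity = 1.0,
                                                    length_mm = 5)),
               "fraction")
})

test_that("pullback frame count, ordering and carina frame", {
  an <- generate_bifurcation(plain_params())
  pb <- generate_oct_pullback(an, "MV", 0.5)
  expect_length(pb$frames, floor(30 / 0.5) + 1L)   # 61
  s <- vapply(pb$frames, function(f) attr(f, "arclength"), numeric(1L))
  expect_true(all(diff(s) < 0))                    # distal -> proximal
  expect_lte(abs(s[pb$carina_frame_index] - an$carina$arclength),
             pb$frame_spacing / 2)
  expect_error(generate_oct_pullback(an, "MV", 40), "exceeds")
})

test_that("dropout sampler controls missing arcs", {
  an <- generate_bifurcation(plain_params())
  pb <- generate_oct_pullback(an, "MV", 1.0)       # no sampler
  expect_true(all(vapply(pb$frames,
                         function(f) !anyNA(f$outer_radius), logical(1L))))
  pb2 <- generate_oct_pullback(an, "MV", 1.0,
                               dropout_sampler = function(i) c(30, 120))
  expect_true(all(vapply(pb2$frames,
                         function(f) anyNA(f$outer_radius), logical(1L))))
})

test_that("composition arcs cover the requested fractions within one bin", {
  an <- generate_bifurcation(stenosed_params(slice_spacing = 0.25))
  pb <- generate_oct_pullback(an, "MV", 2.0, seed = 3)
  bin <- 360 / length(an$angles_deg)
  for (fr in pb$frames[c(2, 6, 11)]) {
    s <- attr(fr, "arclength")
    want <- resample_polyline(an$mv$comp, an$mv$s, s)
    got <- (fr$composition$end_deg - fr$composition$start_deg) %% 360
    names(got) <- fr$composition$tissue
    for (tis in names(got))
      expect_lte(abs(got[[tis]] - 360 * want[match(tis, c("lipid", "fibrous",
                                                          "calcified"))]),
                 bin)
  }
})

test_that("slice area from generated contours matches the analytic profile within 1%", {
  an <- generate_bifurcation(stenosed_params(slice_spacing = 0.25))
  pb <- generate_oct_pullback(an, "MV", 1.0)
  for (fr in pb$frames[seq(1, 30, by = 5)]) {
    s <- attr(fr, "arclength")
    th <- fr$angles_deg * pi / 180
    poly_a <- polygon_area(fr$lumen_radius * cos(th),
                           fr$lumen_radius * sin(th))
    true_a <- pi * (branch_diameter(an, "MV", s) / 2)^2
    expect_lt(abs(poly_a - true_a) / true_a, 0.01)
  }
})

test_that("projection requires 30 degrees separation and is view-dependent", {
  an <- generate_bifurcation(plain_params())
  expect_error(project_to_planes(an, 0, 20), "30 degrees")
  # straight anatomy lies along x: both views see a straight silhouette
  pr <- project_to_planes(an, 0, 90)
  expect_equal(max(abs(pr$view_a$mv$points[, 2L])), 0)
  # curved anatomy: orthogonal views differ
  anc <- generate_bifurcation(plain_params(curvature_radius = 40))
  prc <- project_to_planes(anc, 0, 90)
  expect_gt(max(abs(prc$view_a$mv$points[, 2L] -
                    prc$view_b$mv$points[, 2L])), 0.5)
})

test_that("bench variant: uniform silicone wall, no plaque", {
  an <- generate_bifurcation(stenosed_params())
  bench <- generate_bench_variant(an, 1.0)
  expect_equal(bench$mv$wall, rep(1.0, length(bench$mv$s)))
  expect_identical(bench$material, "silicone")
  # material tag resolves to the Neo-Hookean silicone C10
  expect_equal(fix_table$soft$silicone$C[1L], 0.154)
  expect_true(all(is.na(plaque_score_at(bench, "MV", c(5, 10, 15)))))
  expect_error(generate_bench_variant(an, 0), "> 0")
})

test_that("procedure templates follow the technique grammar", {
  devs <- fix_devices()
  prov <- generate_procedure("provisional", devs)
  expect_identical(vapply(prov$steps, `[[`, "", "action"),
                   c("stent", "pot", "sb_open", "kbi"))
  cul <- generate_procedure("culotte", devs)
  stent_steps <- Filter(function(s) s$action == "stent", cul$steps)
  expect_length(stent_steps, 2L)
  expect_setequal(vapply(stent_steps, `[[`, "", "branch"), c("MV", "SB"))
  # SB stent comes first in a culotte
  expect_identical(cul$steps[[1L]]$branch, "SB")
  expect_error(generate_procedure("provisional", list()), "empty device")
  expect_error(generate_procedure("TAP", devs[c("mv_stent")]), "requires")
})

test_that("anatomy and pullback exports are plain text", {
  an <- generate_bifurcation(plain_params(n_angles = 32L))
  dir <- withr::local_tempdir()
  write_anatomy(an, file.path(dir, "anat"), h = 0.6)
  expect_true(file.exists(file.path(dir, "anat", "lumen.stl")))
  expect_true(file.exists(file.path(dir, "anat", "centerline_mv.csv")))
  pb <- generate_oct_pullback(an, "SB", 2.0)
  man <- write_pullback(pb, file.path(dir, "pb"))
  meta <- jsonlite::read_json(man)
  expect_equal(meta$n_frames, length(pb$frames))
})
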