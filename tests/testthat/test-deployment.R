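# Slice-wise deployment surrogate: equilibrium, recoil, procedure replay.

test_that("wall pressure: zero at reference, composes the silicone example", {
  an <- generate_bench_variant(generate_bifurcation(plain_params()), 1.0)
  st <- deployment_state(an, deployment_config(slice_spacing = 0.5),
                         fix_table)
  expect_equal(wall_pressure(st, "MV", 10L, st$mv$slices$r0[10L]), 0)
  # silicone slice at 10% circumferential stretch: p = (t/r) * sigma(1.1)
  r0 <- st$mv$slices$r0[10L]; r <- 1.1 * r0; t <- st$mv$slices$thickness[10L]
  expect_equal(wall_pressure(st, "MV", 10L, r),
               (t / r) * uniaxial_stress(fix_table$soft$silicone, 1.1))
  expect_error(wall_pressure(st, "MV", 10L, 0.3 * r0), "half")
})

test_that("wall pressure is ordered by plaque stiffness at 20% stretch", {
  st_soft <- fix_state(scored_params(-1))
  st_stiff <- fix_state(scored_params(1))
  i <- which.min(abs(st_soft$mv$slices$arclength - 10))
  r0 <- st_soft$mv$slices$r0[i]
  expect_gt(wall_pressure(st_stiff, "MV", i, 1.2 * r0),
            wall_pressure(st_soft, "MV", i, 1.2 * r0))
})

test_that("ring pressure: unloaded at plastic set, slope linear in strut area", {
  alloy <- fix_table$alloys$MP35N
  mk_layer <- function(area) list(r_set = 1.5, r_peak = 1.5, alloy = alloy,
                                  area = area, w = 1.6, thickness = 0.09)
  expect_equal(ring_pressure(mk_layer(0.0065), 1.5), 0)
  dr <- 1e-5
  s1 <- ring_pressure(mk_layer(0.0065), 1.5 + dr) / dr
  s2 <- ring_pressure(mk_layer(0.0130), 1.5 + dr) / dr
  expect_equal(s2 / s1, 2, tolerance = 1e-9)
})

test_that("inflation: identity at zero pressure, monotone in pressure, clamped", {
  st <- fix_state()
  bal <- balloon_spec(3.0, 15, "semi_compliant", nominal_pressure = 6)
  w <- list(branch = "MV", range = c(5, 15))
  expect_identical(inflate(st, bal, 0, w), st)
  set.seed(7)
  prev <- st
  for (P in c(4, 8, 12, 16)) {
    cur <- inflate(st, bal, P, w)
    expect_true(all(cur$mv$slices$r >= prev$mv$slices$r - 1e-5),
                label = sprintf("P=%g", P))
    # clamp: never beyond the balloon (a balloon smaller than the lumen
    # leaves the slice at its reference radius)
    r_b <- balloon_diameter_at_pressure(bal, P, fix_table) / 2
    expect_true(all(cur$mv$slices$r <= pmax(cur$mv$slices$r0, r_b) + 1e-9))
    prev <- cur
  }
  # slices outside the window untouched
  cur <- inflate(st, bal, 12, w)
  out <- cur$mv$slices$arclength < 5 | cur$mv$slices$arclength > 15
  expect_identical(cur$mv$slices$r[out], st$mv$slices$r[out])
  expect_identical(cur$sb$slices$r, st$sb$slices$r)
})

test_that("recoil: unstented slices return to r0, stented retain plastic gain", {
  st <- fix_state()
  bal <- balloon_spec(3.5, 30, "non_compliant", nominal_pressure = 8)
  w <- list(branch = "MV", range = c(0, 30))
  up <- inflate(st, bal, 14, w)
  expect_true(any(up$mv$slices$r > st$mv$slices$r))
  down <- deflate_recoil(up, w)
  expect_equal(down$mv$slices$r, down$mv$slices$r0, tolerance = 1e-9)
  expect_true(all(down$mv$slices$r <= up$mv$slices$r + 1e-12))
  # with a stent: residual gain and increased plastic set
  stn <- deploy_stent(st, stent_device("integrity_like", 3.0, 18, 16), 16,
                      list(mv = c(7, 25), sb = NULL))
  idx <- stentsim:::window_slices(stn, "MV", c(8.5, 13))  # in-lesion slices
  expect_true(all(stn$mv$slices$r[idx] > st$mv$slices$r[idx]))
  sets <- vapply(idx, function(i) stn$mv$layers[[i]][[1L]]$r_set, numeric(1L))
  expect_true(all(sets > stn$config$crimp_diameter / 2))
})

test_that("stent deployment: SB untouched, MSD clamped, jailing marked", {
  st <- fix_state()
  dev <- stent_device("integrity_like", 3.0, 18, 16)
  stn <- deploy_stent(st, dev, 16, list(mv = c(7, 25), sb = NULL))
  expect_identical(stn$sb$slices$r, st$sb$slices$r)
  expect_true(any(stn$sb$slices$jailed))      # window crosses the carina
  msd <- msd_profile(stn, "MV")
  d_bal <- balloon_diameter_at_pressure(stentsim:::device_balloon(dev), 16,
                                        fix_table)
  expect_true(all(msd$diameter_mm <= d_bal + 1e-9, na.rm = TRUE))
})

test_that("culotte leaves two layers on the proximal MV and caps at two", {
  st <- fix_state(plain_params())
  cul <- generate_procedure("culotte", fix_devices())
  fin <- run_procedure(st, cul)
  nlay <- vapply(fin$mv$layers, length, integer(1L))
  prox <- fin$mv$slices$arclength >= fin$carina_arclength - 4 &
    fin$mv$slices$arclength <= fin$carina_arclength - 0.5
  expect_true(any(nlay[prox] == 2L))
  expect_true(all(nlay <= 2L))
})

test_that("POT: confined to the proximal MV, never shrinks the lumen there", {
  st <- fix_state()
  dev0 <- stent_device("integrity_like", 3.0, 18, 16)
  stn <- deploy_stent(st, dev0, 16, list(mv = c(7, 25), sb = NULL))
  dev <- balloon_device("non_compliant", 3.5, 8, 18)
  after <- pot(stn, dev, 18)
  distal <- after$mv$slices$arclength > after$carina_arclength + 1e-9
  expect_identical(after$mv$slices$r[distal], stn$mv$slices$r[distal])
  prox <- !distal
  expect_true(all(after$mv$slices$r[prox] >= stn$mv$slices$r[prox] - 1e-5))
  # the explicit-window variant shifts proximally
  off <- pot(stn, dev, 18, window = c(after$carina_arclength - 12,
                                      after$carina_arclength - 4))
  touched <- which(abs(off$mv$slices$r - stn$mv$slices$r) > 1e-12)
  expect_true(all(off$mv$slices$arclength[touched] <=
                    after$carina_arclength - 4 + 1e-9))
})

test_that("SB strut opening: ostium area strictly increases, MV untouched", {
  st <- fix_state()
  stn <- deploy_stent(st, stent_device("integrity_like", 3.0, 18, 16), 16,
                      list(mv = c(7, 25), sb = NULL))
  a0 <- ostium_area(stn)
  op <- sb_open(stn, balloon_device("semi_compliant", 2.5, 4, 6), 6)
  expect_gt(ostium_area(op), a0)
  expect_identical(op$recross_cell, "distal")
  expect_identical(op$mv$slices$r, stn$mv$slices$r)
  expect_false(any(op$sb$slices$jailed[
    op$sb$slices$arclength <= 2 * op$sb$slices$r0[1L]]))
})

test_that("KBI: combined clamp, proximal MLD non-decreasing, SB distal safe", {
  st <- fix_state()
  stn <- deploy_stent(st, stent_device("integrity_like", 3.0, 18, 16), 16,
                      list(mv = c(7, 25), sb = NULL))
  stn <- pot(stn, balloon_device("non_compliant", 3.5, 8, 18), 18)
  b1 <- balloon_device("compliant", 3.0, 15, 12)
  b2 <- balloon_device("compliant", 3.0, 15, 12)
  after <- kbi(stn, b1, b2, 12, 12)
  # equal balloons: the overlap clamp is sqrt(2) x the single radius
  r1 <- balloon_diameter_at_pressure(stentsim:::device_balloon(b1), 12,
                                     fix_table) / 2
  over <- after$mv$slices$arclength >= after$carina_arclength - 3 &
    after$mv$slices$arclength <= after$carina_arclength
  expect_true(all(after$mv$slices$r[over] <= sqrt(2) * r1 + 1e-9))
  prox <- after$mv$slices$arclength <= after$carina_arclength
  expect_true(all(after$mv$slices$r[prox] >= stn$mv$slices$r[prox] - 1e-5))
  distal_sb <- after$sb$slices$arclength > b2$length_mm
  expect_identical(after$sb$slices$r[distal_sb], stn$sb$slices$r[distal_sb])
})

test_that("malapposition: undersized stent leaves positive gaps", {
  st <- fix_state(plain_params())        # 3.5 mm vessel
  dev <- stent_device("integrity_like", 2.5, 18, 10)   # undersized
  stn <- deploy_stent(st, dev, 10, list(mv = c(7, 25), sb = NULL))
  gaps <- malapposition_map(stn)
  expect_true(all(gaps$gap_mm >= 0))
  expect_gt(max(gaps$gap_mm), 0.05)
  # a well-sized stent apposes: zero gaps
  stw <- deploy_stent(st, stent_device("integrity_like", 3.5, 18, 16), 16,
                      list(mv = c(7, 25), sb = NULL))
  expect_lt(max(malapposition_map(stw)$gap_mm), 1e-6)
})

test_that("procedure replay: empty table, step chaining, ordering warning", {
  st <- fix_state()
  empty <- structure(list(template = "provisional", steps = list()),
                     class = "procedure_table")
  expect_identical(run_procedure(st, empty), st)
  tab <- generate_procedure("provisional", fix_devices())
  fin <- run_procedure(st, tab)
  expect_length(fin$history, length(tab$steps))
  # chaining: replay step-by-step from saved states
  s1 <- st
  for (stp in tab$steps) {
    one <- tab; one$steps <- list(stp); one$steps[[1L]]$step <- 1L
    s1 <- run_procedure(s1, one)
  }
  strip <- function(x) { x$history <- NULL; x$log <- NULL; x }
  expect_identical(serialize(strip(fin), NULL), serialize(strip(s1), NULL))
  # POT before any stent raises an ordering warning
  perm <- tab; perm$steps <- tab$steps[c(2, 1, 3, 4)]
  perm$steps <- lapply(seq_along(perm$steps), function(i) {
    s <- perm$steps[[i]]; s$step <- i; s })
  expect_warning(run_procedure(st, perm), "before any")
})

test_that("a bench provisional sequence with SB stent and KBI runs end to end", {
  an <- generate_bench_variant(generate_bifurcation(plain_params()), 1.0)
  st <- deployment_state(an, deployment_config(slice_spacing = 0.5),
                         fix_table)
  devs <- fix_devices()
  steps <- list(
    stentsim:::procedure_step(1L, "stent", "MV", devs$mv_stent, 16),
    stentsim:::procedure_step(2L, "pot", "MV", devs$pot_balloon, 18),
    stentsim:::procedure_step(3L, "sb_open", "SB", devs$sb_balloon, 6),
    stentsim:::procedure_step(4L, "stent", "SB", devs$sb_stent, 14,
                              placement = list(mode = "protrusion",
                                               value_mm = 1)),
    stentsim:::procedure_step(5L, "kbi", "MV", devs$kbi_mv, 12))
  steps[[5L]]$device_sb <- devs$kbi_sb
  tab <- structure(list(template = "provisional", steps = steps),
                   class = "procedure_table")
  fin <- run_procedure(st, tab)
  expect_length(fin$stents, 2L)
  expect_length(fin$history, 5L)
  expect_true(all(fin$mv$slices$r >= fin$mv$slices$r0 - 1e-9))
})

test_that("identical procedures expand stiff plaque less than soft plaque", {
  tab <- generate_procedure("provisional", fix_devices())
  fin_stiff <- run_procedure(fix_state(scored_params(1)), tab)
  fin_soft <- run_procedure(fix_state(scored_params(-1)), tab)
  expect_lt(in_lesion_mld(fin_stiff), in_lesion_mld(fin_soft))
})
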