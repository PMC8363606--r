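#' @title Pipeline configuration and orchestration
#' @description End-to-end orchestration of the platform: synthesize inputs,
#'   reconstruct the bifurcation, replay the procedure, reconstruct the
#'   stent, run the hemodynamic surrogate and produce agreement reports —
#'   with explicit seeds and bit-stable on-disk outputs. Procedure tables are
#'   serialized as JSON records with the step/action/device/placement schema
#'   used throughout.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed integer seed used for all synthetic sampling.
#' @param anatomy an [anatomy_params] (default: the reference stenosed case).
#' @param frame_spacing OCT frame spacing, mm.
#' @param slice_spacing deployment slice spacing, mm.
#' @param view_angles biplane view angles, degrees.
#' @param material_table_path optional alternative material table JSON.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("stentsim_"), seed = 1L,
                            anatomy = NULL, frame_spacing = 0.5,
                            slice_spacing = 0.25, view_angles = c(0, 90),
                            material_table_path = NULL) {
  if (is.null(anatomy))
    anatomy <- anatomy_params(
      stenoses = data.frame(branch = "MV", center_mm = 10, severity = 0.6,
                            length_mm = 8),
      seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 anatomy = anatomy, frame_spacing = frame_spacing,
                 slice_spacing = slice_spacing, view_angles = view_angles,
                 material_table_path = material_table_path),
            class = "pipeline_config")
}

#' Write / read a procedure table as JSON
#'
#' Records mirror the procedural-step schema: step, action, branch, device
#' (kind, preset, diameter_mm, length_mm, compliance_class, pressure_atm),
#' pressure_atm, placement (mode, value_mm, reference_step). Steps must be
#' numbered consecutively and placement references must point backward.
#'
#' @param table a `procedure_table`.
#' @param path JSON file path.
#' @return `path` (write) / `procedure_table` (read).
#' @export
write_procedure_json <- function(table, path) {
  stopifnot(inherits(table, "procedure_table"))
  jsonlite::write_json(list(template = table$template, steps = table$steps),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_procedure_json
#' @export
read_procedure_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  steps <- lapply(raw$steps, function(st) {
    if (is.null(st$device))
      stop(sprintf("step #%s has no device", st$step))
    st$step <- as.integer(st$step)
    st
  })
  nums <- vapply(steps, function(s) s$step, integer(1L))
  if (!identical(nums, seq_along(steps)))
    stop("steps must be numbered consecutively from 1")
  for (st in steps) {
    ref <- st$placement$reference_step
    if (!is.null(ref) && ref >= st$step)
      stop(sprintf("step #%d references a later step", st$step))
  }
  structure(list(template = raw$template, steps = steps),
            class = "procedure_table")
}

#' Synthesize all pipeline inputs to disk
#'
#' Anatomy (STL/CSV/JSON), MV and SB pullbacks (CSV frames + manifest) and
#' biplane projections (CSV). Deterministic: the same config yields
#' checksum-identical files.
#'
#' @param config a [pipeline_config].
#' @return list with the generated objects and file paths.
#' @export
cmd_synth <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  anatomy <- generate_bifurcation(config$anatomy)
  paths <- write_anatomy(anatomy, file.path(config$out_dir, "anatomy"))
  pb_mv <- generate_oct_pullback(anatomy, "MV", config$frame_spacing,
                                 seed = config$seed)
  pb_sb <- generate_oct_pullback(anatomy, "SB", config$frame_spacing,
                                 seed = config$seed + 1L)
  write_pullback(pb_mv, file.path(config$out_dir, "pullback_mv"))
  write_pullback(pb_sb, file.path(config$out_dir, "pullback_sb"))
  proj <- project_to_planes(anatomy, config$view_angles[1L],
                            config$view_angles[2L])
  for (v in names(proj)) {
    for (br in c("mv", "sb")) {
      utils::write.csv(as.data.frame(proj[[v]][[br]]$points),
                       file.path(config$out_dir,
                                 sprintf("projection_%s_%s.csv", v, br)),
                       row.names = FALSE)
    }
  }
  list(anatomy = anatomy, pullback_mv = pb_mv, pullback_sb = pb_sb,
       projections = proj, paths = paths)
}

#' Reconstruct the bifurcation from synthesized inputs
#'
#' Biplane centerline fusion, pullback alignment with outer-border rules,
#' branch lofting and implicit merging.
#'
#' @param config a [pipeline_config].
#' @param inputs result of [cmd_synth] (re-run if NULL).
#' @return list with centerlines, lofted branches and the merged geometry.
#' @export
cmd_reconstruct <- function(config, inputs = NULL) {
  if (is.null(inputs)) inputs <- cmd_synth(config)
  an <- inputs$anatomy
  pr <- inputs$projections
  cl_mv <- centerline_from_biplane(pr$view_a$mv, pr$view_b$mv,
                                   carina_arclength = an$carina$arclength)
  cl_sb <- centerline_from_biplane(pr$view_a$sb, pr$view_b$sb, branch = "SB",
                                   carina_arclength = 0)
  pos_mv <- suppressWarnings(align_pullback(inputs$pullback_mv, cl_mv))
  pos_sb <- suppressWarnings(align_pullback(inputs$pullback_sb, cl_sb))
  mv <- loft_branch(pos_mv)
  sb <- loft_branch(pos_sb)
  geom <- merge_branches(mv, sb)
  write_stl_ascii(geom$lumen, file.path(config$out_dir, "recon_lumen.stl"))
  utils::write.csv(geom$mv$s, file.path(config$out_dir, "recon_mv_s.csv"),
                   row.names = FALSE)
  jsonlite::write_json(pos_mv$discard,
                       file.path(config$out_dir, "discard_log_mv.json"),
                       dataframe = "rows", digits = NA)
  list(centerline_mv = cl_mv, centerline_sb = cl_sb, mv = mv, sb = sb,
       geometry = geom)
}

#' Replay a procedure on the synthetic anatomy
#'
#' @param config a [pipeline_config].
#' @param procedure a `procedure_table` or path to a procedure JSON.
#' @param inputs optional [cmd_synth] result.
#' @return final `deployment_state` (snapshots in `$history`).
#' @export
cmd_simulate <- function(config, procedure, inputs = NULL) {
  if (is.character(procedure)) procedure <- read_procedure_json(procedure)
  for (st in procedure$steps) {
    d <- st$device
    if (identical(d$kind, "stent") &&
        !d$preset %in% c("integrity_like", "onyx_like", "synergy_like"))
      stop(sprintf("step #%d: unknown stent preset '%s'", st$step, d$preset))
  }
  if (is.null(inputs)) inputs <- cmd_synth(config)
  tab <- if (is.null(config$material_table_path)) material_table()
         else material_table(config$material_table_path)
  st0 <- deployment_state(inputs$anatomy,
                          deployment_config(slice_spacing =
                                              config$slice_spacing),
                          table = tab)
  fin <- run_procedure(st0, procedure)
  write_deployment_csv(fin, file.path(config$out_dir, "deployment.csv"))
  jsonlite::write_json(fin$log, file.path(config$out_dir, "procedure_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  fin
}

#' Reconstruct the deployed stent from simulated OCT strut detections
#'
#' @param config a [pipeline_config].
#' @param state a post-procedure `deployment_state`.
#' @param stent_id which stent.
#' @param frame_spacing detection frame spacing, mm.
#' @return list with the detection cloud, match and reconstructed geometry.
#' @export
cmd_recon_stent <- function(config, state, stent_id = 1L,
                            frame_spacing = 0.2) {
  truth <- deployed_stent_geometry(state, stent_id)
  cl <- state$centerlines[[truth$branch]]
  cloud <- simulate_strut_detections(truth, cl, frame_spacing)
  u <- unroll(cloud)
  match <- register_pattern(u, truth$design)
  sl <- anat_branch(state, truth$branch)$slices
  rec <- wrap_to_3d(match, cl,
                    data.frame(arclength = sl$arclength, r = sl$r))
  mesh <- add_strut_volume(rec)
  write_stl_ascii(mesh, file.path(config$out_dir, "stent_recon.stl"))
  write_strut_cloud(cloud, file.path(config$out_dir, "strut_points.csv"))
  list(truth = truth, cloud = cloud, match = match, geometry = rec,
       mesh = mesh)
}

#' Pre/post TAWSS comparison on the simulated case
#'
#' @param config a [pipeline_config].
#' @param state post-procedure `deployment_state`.
#' @param inputs optional [cmd_synth] result.
#' @return list with `pre` and `post` `wss_profile`s.
#' @export
cmd_flow <- function(config, state, inputs = NULL) {
  if (is.null(inputs)) inputs <- cmd_synth(config)
  an <- inputs$anatomy
  fc <- flow_conditions()
  pre <- tawss_profile(as.data.frame.profile(mld_profile(an, "MV")),
                       as.data.frame.profile(mld_profile(an, "SB")),
                       fc, an$carina$arclength)
  post <- tawss_profile(as.data.frame.profile(mld_profile(state, "MV")),
                        as.data.frame.profile(mld_profile(state, "SB")),
                        fc, an$carina$arclength)
  write_wss_csv(pre, file.path(config$out_dir, "tawss_pre.csv"), "pre")
  write_wss_csv(post, file.path(config$out_dir, "tawss_post.csv"), "post")
  list(pre = pre, post = post)
}

as.data.frame.profile <- function(p) {
  data.frame(arclength_mm = p$arclength_mm, diameter_mm = p$diameter_mm)
}

#' Agreement report between simulated and reference profiles
#'
#' @param config a [pipeline_config].
#' @param pair_sets named list of paired-difference frames ([coregister]).
#' @return the `ba_report`, also written as CSV/JSON/markdown.
#' @export
cmd_compare <- function(config, pair_sets) {
  rep <- report_tables(pair_sets)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep, file.path(config$out_dir, "agreement.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep, file.path(config$out_dir, "agreement.json"),
                       dataframe = "rows", digits = NA)
  writeLines(format_ba_markdown(rep),
             file.path(config$out_dir, "agreement.md"))
  rep
}

#' Run the full pipeline
#'
#' synth -> reconstruct -> simulate -> recon-stent -> flow -> compare, with
#' fixed seeds throughout; outputs are written under the config's out_dir
#' and are checksum-stable across runs.
#'
#' @param config a [pipeline_config].
#' @param procedure a `procedure_table` (default: provisional with POT and
#'   KBI, a representative one-stent technique).
#' @return list with all stage results and the agreement report.
#' @export
run_pipeline <- function(config = pipeline_config(), procedure = NULL) {
  if (is.null(procedure)) procedure <- default_procedure()
  inputs <- cmd_synth(config)
  recon <- cmd_reconstruct(config, inputs)
  state <- cmd_simulate(config, procedure, inputs)
  stent <- cmd_recon_stent(config, state)
  flow <- cmd_flow(config, state, inputs)
  pairs <- list(
    `MV lumen` = coregister(mld_profile(recon$mv),
                            mld_profile(inputs$anatomy, "MV")),
    `SB lumen` = coregister(mld_profile(recon$sb),
                            mld_profile(inputs$anatomy, "SB")))
  report <- cmd_compare(config, pairs)
  list(inputs = inputs, recon = recon, state = state, stent = stent,
       flow = flow, report = report)
}

#' Default provisional procedure (MV stent, POT, SB opening, KBI)
#'
#' @param stent_diameter,stent_length MV stent size, mm.
#' @return a `procedure_table`.
#' @export
default_procedure <- function(stent_diameter = 3.0, stent_length = 18) {
  generate_procedure("provisional", list(
    mv_stent = stent_device("integrity_like", stent_diameter, stent_length,
                            16),
    pot_balloon = balloon_device("non_compliant", 3.5, 8, 18),
    sb_balloon = balloon_device("semi_compliant", 2.5, 4, 6),
    kbi_mv = balloon_device("compliant", 3.5, 15, 12),
    kbi_sb = balloon_device("semi_compliant", 2.75, 8, 14)))
}
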