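# Shared fixtures, all generated in code. Coarser slice spacings than the
# defaults keep the suite fast; the convergence test exercises the default.

fix_table <- material_table()

# straight 3.5 mm untapered vessel, no stenosis
plain_params <- function(slice_spacing = 0.5, ...) {
  anatomy_params(proximal_mv_diameter = 3.5, distal_mv_diameter = 3.5,
                 taper_rate = 0, slice_spacing = slice_spacing, ...)
}

# reference stenosed case: 60% diameter stenosis mid-MV
stenosed_params <- function(slice_spacing = 0.5, ...) {
  anatomy_params(stenoses = data.frame(branch = "MV", center_mm = 10,
                                       severity = 0.6, length_mm = 8),
                 slice_spacing = slice_spacing, ...)
}

fix_devices <- function() {
  list(mv_stent = stent_device("integrity_like", 3.0, 18, 16),
       sb_stent = stent_device("onyx_like", 2.5, 12, 14),
       pot_balloon = balloon_device("non_compliant", 3.5, 8, 18),
       sb_balloon = balloon_device("semi_compliant", 2.5, 4, 6),
       kbi_mv = balloon_device("compliant", 3.5, 15, 12),
       kbi_sb = balloon_device("semi_compliant", 2.75, 8, 14))
}

# deployment state on the stenosed case at 0.5 mm slices
fix_state <- function(params = stenosed_params(), spacing = 0.5) {
  deployment_state(generate_bifurcation(params),
                   deployment_config(slice_spacing = spacing),
                   table = fix_table)
}

# uniform-composition anatomy whose plaque score is `score` everywhere
scored_params <- function(score, slice_spacing = 0.5) {
  comp <- if (score >= 0) {
    f <- score / 2
    function(s, branch) c(lipid = 0, fibrous = 1 - f, calcified = f)
  } else {
    f <- -score / 2
    function(s, branch) c(lipid = f, fibrous = 1 - f, calcified = 0)
  }
  anatomy_params(stenoses = data.frame(branch = "MV", center_mm = 10,
                                       severity = 0.6, length_mm = 8),
                 composition_map = comp, slice_spacing = slice_spacing)
}

# mean in-lesion diameter of the final MV state
in_lesion_mld <- function(state, center = 10, halfwidth = 4) {
  sl <- state$mv$slices
  sel <- abs(sl$arclength - center) <= halfwidth
  mean(2 * sl$r[sel])
}
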