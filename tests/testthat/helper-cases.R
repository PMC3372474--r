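# Shared fixtures: fast synthetic configurations for unit tests.  The
# preset desk grids are exercised by scripts/acceptance.R; unit tests use
# coarser colonies so the suite stays interactive.

# A fat synthetic branch: same morphology class as the branching presets
# but wide enough that the 8-cells-across rule is met on small grids.
test_branch_preset <- function() {
  structure(
    list(name = "synthetic branch", coral = coral_shape("cylinder", 0.005, 0.008),
         scenario = "steady", porosity = 0.43, porosity_assumed = TRUE,
         alpha_range = c(0.13, 0.28), Re_low = NA_real_, Re_high = NA_real_,
         t_on_s = NA_real_, table6_model_low_K = 0.35,
         table6_model_high_K = NA_real_,
         desk_resolution = c(44L, 26L, 24L)),
    class = "species_preset")
}
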