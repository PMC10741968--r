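## Shared fixtures: preset systems and coarse-but-adequate mesh controls
## used across tests to keep runtimes moderate.

dopc_system <- function() bilayer_system(preset_parameters("DOPC"))
pops_system <- function() bilayer_system(preset_parameters("POPC_POPS_3to1"))

## radial mesh for tests that need many solves
test_rmesh <- list(h0 = 0.01, grow = 1.08)

## patch params with a given splay modulus / spontaneous curvature
inclusion_params <- function(B = 10, J0 = 0, preset = "inclusion_common") {
  p <- preset_parameters(preset)
  p$B <- B
  p$J0 <- J0
  p
}

## deviation profile helper
thickness_deviation <- function(result) {
  pr <- thickness_profile(result)
  h2 <- result$system$upper$h + result$system$lower$h
  data.frame(r = pr$r, dev = pr$thickness - h2)
}
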