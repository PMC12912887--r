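# Shared small designs and profiles for the simulation-backed tests.

one_background_design <- function(fish_per_cell = 5, seed = 1,
                                  background = "black") {
  bgs <- default_backgrounds()
  experiment_design(backgrounds = bgs[bgs$background == background, ],
                    fish_per_cell = fish_per_cell, seed = seed)
}

# all populations share one profile: no population x time signal
null_profiles <- function(populations = c("Gizan", "Jeddah", "Khaybar",
                                          "Nawan"),
                          ...) {
  prof <- population_profile(...)
  stats::setNames(rep(list(prof), length(populations)), populations)
}

noiseless_profiles <- function(populations = c("Gizan", "Jeddah", "Khaybar",
                                               "Nawan"), ...) {
  null_profiles(populations, fish_sd = 0, resid_sd = 0, ...)
}
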