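# Shared fixtures, computed once per test run and cached.

.fx <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_lib <- function() cached("lib", make_tissue_library("normal"))
fx_model <- function() cached("model", build_limb())

# a small fixed coarse mesh of the default limb under the conventional
# configuration, shared by the exact-identity tests
fx_mesh_coarse <- function() cached("mesh_coarse", {
  model <- fx_model()
  cfg <- electrode_preset("conventional", model)
  generate_mesh(model, place_electrodes(model, cfg), "coarse")
})

# 50 kHz single-frequency sweeps at coarse resolution, shared between the
# trend and configuration-ordering tests
fx_sweep <- function(config_name, variable) {
  key <- paste0("sweep_", config_name, "_", variable)
  cached(key, {
    values <- if (variable == "muscle") c(41, 46, 51, 56) else c(3, 5, 7, 9)
    run_sweep(electrode_preset(config_name, fx_model()), fx_lib(),
              variable, values, 5e4, fx_model(), "coarse", gate = FALSE)
  })
}

fx_slope <- function(config_name, variable = "muscle", parameter = "X") {
  slope_from_sweep(fx_sweep(config_name, variable), parameter, 5e4)
}
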