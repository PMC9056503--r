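# shared fixtures built in code

# per-second decay constants of the packaged isotopes
lam_s <- function() setNames(isotopes()$lambda_per_min / 60, isotopes()$name)

# exact expected bin counts for given amplitudes (cps at end of irradiation)
# on 10-s bins over [start_min, start_min + duration_min]
model_series <- function(amplitudes, start_min = 10, duration_min = 29,
                         bin_width_s = 10) {
  spec <- scenario_spec(amplitudes = amplitudes, f18O = 0,
                        background_rate = 0,
                        pre = list(start_min = start_min,
                                   duration_min = duration_min))
  simulate_count_series(spec, "pre", bin_width_s = bin_width_s, noise = FALSE)
}

water_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- sp_material("water")
    tab
  }
})
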