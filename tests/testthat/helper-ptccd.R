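# shared fixtures: the reference detector of the simulation study
ref_params <- function() cascade_params()
ref_budget <- function() noise_budget(ref_params())

# a noiseless, variance-free chain: every stage deterministic
ideal_params <- function() {
  cascade_params(q_abs = 1, gain_mean = 100, gain_sd = 0, transmission = 1,
                 g_adc = 0.2, read_noise_e = 0, digitization_var_adu2 = 0)
}

# small detector config for fast end-to-end runs
small_config <- function(...) detector_config(...)

expect_within_se <- function(observed, expected, se, k = 3) {
  expect_lt(abs(observed - expected), k * se)
}
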