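# Shared subjects and small controls used across test files.

diaz_subject <- function() adipose_subject(73.7, 1.75, 36, "male")
tremblay_subject <- function() adipose_subject(60.3, 1.72, 36, "male")
lean_subject <- function() adipose_subject(60, 1.70, 35, "male")

# a small, fast control: fewer macrophages, default physics
fast_control <- function(...) {
  sim_control(inflammation = inflammation_params(n_macrophages = 50), ...)
}

# deterministic growth parameters (no volume noise) for exact checks
noiseless_growth <- function(gender = "male", ...) {
  growth_params(gender = gender, k4 = 0, ...)
}
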