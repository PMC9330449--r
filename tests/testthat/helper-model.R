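# shared fixtures; expensive objects are computed once per test run
ref_params <- hpt_params()
ref_female <- patient_profile("female", 1.67, 63)

.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache, inherits = FALSE))
    assign(key, expr, envir = .test_cache)
  get(key, envir = .test_cache)
}

ref_ic <- function() cached("ref_ic", initial_condition(ref_params))
ref_female_pp <- function() cached("ref_fpp", personalize(hpt_params(), ref_female))
ref_female_ic <- function() cached("ref_fic", initial_condition(ref_female_pp()))

# coarse RTF curve reused across rtf tests
coarse_curve <- function() cached("curve_f25",
  rtf_curve("female", 25, rtf_grid = seq(0, 0.5, by = 0.1)))
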