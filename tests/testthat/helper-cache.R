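# Shared fixtures, computed lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

lean_control <- function(...) {
  fit_control(multistart = 1, quad = c(3, 3, 4), ...)
}

small_cohort <- function() {
  fixture("small_cohort", gen_behavior_cohort(cohort_config(n_subjects = 4,
                                                            seed = 42)))
}

subject_one <- function() {
  coh <- small_cohort()
  coh$trials[coh$trials$subject == "m01", ]
}

cached_ladder <- function() {
  fixture("ladder", fit_all_models(subject_one(), control = lean_control(),
                                   seed = 7))
}
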