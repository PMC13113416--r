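# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Tiny cohort for fast structural tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2, n_sessions = 1, duration_per_trial = 1,
         seed = 101),
    list(...))
  do.call(cohort_config, args)
}

# Mid-size cohort: 3 subjects x 2 sessions x 4 s, enough signal for
# model-behaviour tests without noticeable runtime.
small_table <- function() {
  cached("small_table", build_feature_table(generate_cohort(
    cohort_config(n_subjects = 3, n_sessions = 2, duration_per_trial = 4,
                  seed = 7))))
}

# The generator's default study conditions (8 subjects x 2 sessions x
# 30 s at 2000 Hz, rho = 0.9, default gain table).
default_table <- function() {
  cached("default_table",
         build_feature_table(generate_cohort(cohort_config(seed = 42))))
}

random_profile <- function(seed) {
  set.seed(seed)
  make_activation_profile(s = runif(4), d = runif(4))
}

# fresh scratch directory per call (under the session temp dir)
tmpdir <- function() {
  d <- tempfile("emgdose-test-")
  dir.create(d)
  d
}
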