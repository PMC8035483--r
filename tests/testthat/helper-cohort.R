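# Shared fixtures built in code. The full default cohort run is expensive,
# so it is computed once per test session and memoized for the tests that
# need it (small-world estimability, group-effect recovery).

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small, quick cohort exercising every stage
tiny_cohort <- function(master_seed = 3) {
  memoize(paste0("tiny", master_seed), function() {
    generate_cohort(
      cohort_config(group_sizes = c(CI = 4L, NCI = 4L, HC = 4L),
                    n_regions = 30L, n_volumes = 120L),
      master_seed = master_seed)
  })
}

default_cohort <- function(master_seed = 1) {
  memoize(paste0("cohort", master_seed), function() {
    generate_cohort(master_seed = master_seed)
  })
}

# the full default pipeline run used by the acceptance tests
default_report <- function(master_seed = 1) {
  memoize(paste0("report", master_seed), function() {
    run_pipeline(run_config(master_seed = master_seed, n_null = 20))
  })
}
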