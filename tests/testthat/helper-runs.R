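# Scenario runs shared between acceptance checks (computed once per
# session, at the sizes the presets define).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fun) {
  if (!exists(key, envir = .run_cache)) assign(key, fun(), envir = .run_cache)
  get(key, envir = .run_cache)
}

aqueous_runs <- function(seeds = 1:3) {
  cached_run("aqueous", function()
    lapply(seeds, function(s)
      run_scenario("aqueous", seed = s, until_consumed = 0.95,
                   max_steps = 1500000L)))
}

concentrated_runs <- function(seeds = 1:3) {
  cached_run("concentrated", function()
    lapply(seeds, function(s)
      run_scenario("aqueous-concentrated", seed = s, until_consumed = 0.95,
                   max_steps = 1500000L)))
}

slab_run <- function(name) {
  cached_run(name, function() run_scenario(name, seed = 1, react = FALSE))
}

# median time to 50% monomer consumption over replicas of a preset (cached)
median_t50 <- function(name, seeds = 1:3) {
  cached_run(paste0("t50-", name), function() .t50_values(name, seeds))
}

.t50_values <- function(name, seeds) {
  vapply(seeds, function(s) {
    run <- run_scenario(name, seed = s, until_consumed = 0.5,
                        max_steps = 1200000L)
    cc <- consumption_curve(census_series(run))
    i <- which(cc$fraction <= 0.5)[1]
    if (is.na(i)) Inf else cc$time_ps[i]
  }, 0)
}
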