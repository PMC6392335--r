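# Shared simulated populations for the acceptance checks. Computed once per
# test run (fixed seeds; every run_cell is deterministic given its seed).
pop_cache <- new.env(parent = emptyenv())

cached_population <- function(name, n = 50, seed = 1, overrides = list()) {
  key <- paste(name, n, seed, sep = "_")
  if (!is.null(pop_cache[[key]])) return(pop_cache[[key]])
  pop <- run_population(make_scenario(name, overrides = overrides,
                                      n_reps = n, seed = seed))
  pop_cache[[key]] <- pop
  pop
}

# censored event times carry the cutoff value, so this is a conservative
# per-seed comparison vector
event_times <- function(pop, what = c("clustering", "migration")) {
  what <- match.arg(what)
  if (what == "clustering") pop$records$clustering_time_min
  else pop$records$migration_time_min
}

# one-sided paired sign-flip permutation test for mean(y - x) > 0
perm_test_paired <- function(x, y, n_perm = 2000, seed = 99) {
  set.seed(seed)
  d <- y - x
  obs <- mean(d)
  perm <- replicate(n_perm, mean(d * sample(c(-1, 1), length(d), TRUE)))
  mean(c(perm, obs) >= obs)
}
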