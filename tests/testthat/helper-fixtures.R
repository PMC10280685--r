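# Shared fixtures built in code. Small simulated datasets and a compact
# fitted model reused across test files.

small_sim <- function(N = 120, K = 10, seed = 101, ...) {
  jirt_sim(N, K, seed = seed, ...)
}

# a compact fitted model, memoised so several tests can share it
fitted_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- jirt(sim$Y, sim$RT, XG = 400, seed = 102, truth = sim)
    }
    cache
  }
})
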