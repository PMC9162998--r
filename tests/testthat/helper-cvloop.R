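# Shared fixtures and independent oracles for the test suite.

# Memoize the expensive closed-loop runs so several test files can share them.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}

default_noisefree_run <- function() {
  cached_run("noisefree", function() run_closed_loop(seed = 1, noise = FALSE))
}

default_noisy_run <- function() {
  cached_run("noisy", function() run_closed_loop(seed = 1, noise = TRUE))
}

# Random valid parameter sets that admit a feasible equilibrium.
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    eq_params(S_L = runif(1, 15, 50), S_R = runif(1, 15, 50),
              R = runif(1, 0.3, 1.2), V = runif(1, 18, 32))
  })
}

# Independent equilibrium oracle: plain interval bisection on the volume
# residual over CO, using only the closed-form curve inversions.
bisect_equilibrium <- function(params, constants = model_constants(),
                               lo = 0, hi = 1000, iter = 200) {
  f <- function(CO) {
    P_LA <- constants$P0_L + exp(CO / params$S_L - constants$k_L)
    P_RA <- constants$P0_R + exp(CO / params$S_R - constants$k_R)
    constants$W * CO + constants$G_L * P_LA + constants$G_R * P_RA - params$V
  }
  stopifnot(f(lo) < 0, f(hi) > 0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  CO <- (lo + hi) / 2
  list(CO = CO,
       P_LA = constants$P0_L + exp(CO / params$S_L - constants$k_L),
       P_RA = constants$P0_R + exp(CO / params$S_R - constants$k_R))
}

# Sort-based median, independent of stats::median.
naive_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Closed-form OLS slope, independent of stats::lm.
naive_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
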