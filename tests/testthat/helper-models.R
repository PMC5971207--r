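# Shared small model objects, built once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

two_pop_model <- function() cached("two_pop", build_two_pop())

ring_model <- function() cached("ring", {
  geom <- ring_geometry(50, 50)
  list(geom = geom, net = build_ring_ssn(geom), noise = ring_noise_cov(geom))
})

ma_model <- function() cached("ma", build_multiattractor())

# Population-mean Fano across 100 ms bins of a lambda array (bins x N x trials)
fano_by_bin <- function(lambda, neurons = NULL, seed = 5L, mean_min = 0.01) {
  cb <- poisson_counts(lambda, seed = seed)
  if (is.null(neurons)) neurons <- seq_len(dim(cb)[2])
  vapply(seq_len(dim(cb)[1]), function(b)
    fano_and_correlations(t(cb[b, neurons, ]), mean_min = mean_min)$fano_mean, 1)
}
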