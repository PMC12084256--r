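# Seeded log-uniform parameter draws shared by the property tests.
random_params <- function(n, seed = 1234, lo = 1e-2, hi = 1e2,
                          e0_positive = TRUE) {
  set.seed(seed)
  draws <- matrix(exp(runif(4 * n, log(lo), log(hi))), ncol = 4)
  lapply(seq_len(n), function(i) {
    rate_constants(draws[i, 1], draws[i, 2], draws[i, 3],
                   if (e0_positive) draws[i, 4] else 0)
  })
}
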