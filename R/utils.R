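# Seed plumbing: every stochastic entry point takes an explicit seed and
# evaluates under withr::with_seed so the caller's RNG state is untouched.

# Derive n child seeds deterministically from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
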