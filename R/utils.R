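# Small numeric helpers shared across modules.

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Relative floor applied to probability maps before division, logs or
# exponentiation; one value, used uniformly across the package.
.EPS <- 1e-12

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Deterministic per-unit seed stream derived from a master seed, so cohorts
# are reproducible and independent of subject order.  Kept below 2^31 - 1.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 30011) %% 2147483629L + 1)
}

# One-sample two-sided t test against zero, degenerate-variance aware.
one_sample_t <- function(x) {
  stop_if_not(length(x) >= 2, "need at least 2 values for a group test")
  if (stats::sd(x) == 0) {
    return(list(mean = mean(x), t = NA_real_, df = length(x) - 1L,
                p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = 0)
  list(mean = mean(x), t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
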