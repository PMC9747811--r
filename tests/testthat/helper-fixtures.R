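# Shared fixtures: a compact protocol (short gray segments, CT100 only unless
# stated) keeps simulation-heavy tests fast while preserving the 20-trial
# flash structure every operation depends on.

quick_protocol <- function(contrasts = 100, n_trials = 20,
                           spont_dur = 30, baseline_dur = 5,
                           regime = "mesopic") {
  build_flash_protocol(regime, contrasts = contrasts, n_trials = n_trials,
                       spont_dur = spont_dur, baseline_dur = baseline_dur)
}

# Session with hand-placed spikes for one or more units.
session_from_times <- function(times_by_unit, protocol = quick_protocol(),
                               ...) {
  spikes <- dplyr::bind_rows(lapply(names(times_by_unit), function(u) {
    tibble::tibble(unit_id = u, time = times_by_unit[[u]])
  }))
  rgc_session(spikes, protocol, ...)
}

# Brute-force two-sample KS: D from the empirical CDFs evaluated on the
# pooled values; exact p by enumerating all assignments of the pooled sample
# into the two groups (valid for continuous, tie-free data).
brute_ks <- function(x, y) {
  pooled <- sort(c(x, y))
  ecdf_at <- function(s, v) vapply(v, function(t) mean(s <= t), numeric(1))
  D <- max(abs(ecdf_at(x, pooled) - ecdf_at(y, pooled)))
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  ds <- apply(idx, 2, function(ii) {
    max(abs(ecdf_at(pooled[ii], pooled) - ecdf_at(pooled[-ii], pooled)))
  })
  list(D = D, p = mean(ds >= D - 1e-12))
}

# Exact two-sided Fisher p by full hypergeometric enumeration over all
# tables with the observed margins.
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
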