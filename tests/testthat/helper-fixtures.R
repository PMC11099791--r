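# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# series with a uniform line-of-identity cluster plus an off-line arm:
# runs of equal intervals sweeping lo..hi, each followed by one deviation
# beat at arm_y (kept well off the identity band)
loi_fixture <- function(lo = 520, hi = 700, arm_y = 450, n_runs = 40,
                        run_len = 12) {
  v <- numeric(0)
  bases <- seq(lo, hi, length.out = n_runs)
  for (b in bases) {
    v <- c(v, rep(b, run_len))  # linear (LOI) stretch at this rate
    v <- c(v, arm_y)            # deviation: short-long pair off the LOI
  }
  rr_series(v)
}

# clock-anchored series: constant day_rr except dip_rr during dip hours
sleep_fixture <- function(start_clock = "22:00:00", hours = 9,
                          day_rr = 600, dip_rr = 1200,
                          dip_hours = integer(0)) {
  start <- parse_clock(start_clock)
  v <- numeric(0)
  t <- 0
  while (t < hours * 3600) {
    hr_clock <- floor(((start + t) %% 86400) / 3600)
    rr <- if (hr_clock %in% dip_hours) dip_rr else day_rr
    v <- c(v, rr)
    t <- t + rr / 1000
  }
  rr_series(v, start_clock = start)
}

# tiny linearly separable triple clusters for network convergence checks
toy_triples <- function(n = 60, seed = 3) {
  set.seed(seed)
  a <- matrix(400 + rnorm(3 * n, sd = 15), ncol = 3)
  b <- matrix(1500 + rnorm(3 * n, sd = 15), ncol = 3)
  list(x = rbind(a, b),
       labels = rep(c("BALANCED", "SND"), each = n))
}
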