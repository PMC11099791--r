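# Stochastic sinoatrial exit-block simulator: an internal sinus clock
# modulated by a vagal-tone waveform, plus a probabilistic exit gate that
# blocks beats when vagal tone is high. Conducted intervals accumulate
# across blocked beats, producing the interval bands at integer multiples
# of the base cycle that characterise exit block.

#' Simulation parameters
#'
#' @param t0 Base interval of the internal clock in ms (the cycle length
#'   with zero vagal drive).
#' @param tb Randomness span (ms) applied when the *previous* internal beat
#'   was blocked.
#' @param ebpsf Exit-block probability scale factor: slope of block
#'   probability above the vagal threshold.
#' @param vtdps Vagal-tone-dependent sensitivity, ms of interval
#'   prolongation per unit vagal tone (default 400).
#' @param trand_base Randomness span (ms) after a conducted beat
#'   (default 40).
#' @param vth Vagal-tone threshold below which no block occurs
#'   (default 0.6).
#' @param offset Constant vagal-tone floor (default 0.08).
#' @param resp_amp,resp_period Respiratory oscillation amplitude and period
#'   (defaults 1/8 and 4000 ms, i.e. 15 breaths/min).
#' @param circ_amp,circ_period,circ_shape Circadian term: amplitude 3/8,
#'   period 24 h, and the shape constant applied inside `tanh`.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(t0, tb, ebpsf, vtdps = 400, trand_base = 40,
                       vth = 0.6, offset = 0.08,
                       resp_amp = 1 / 8, resp_period = 4000,
                       circ_amp = 3 / 8, circ_period = 86400000,
                       circ_shape = 1) {
  stopifnot(t0 > 0, tb >= 0, ebpsf >= 0, vtdps >= 0, trand_base >= 0,
            vth > 0, resp_period > 0, circ_period > 0)
  structure(
    list(t0 = t0, tb = tb, ebpsf = ebpsf, vtdps = vtdps,
         trand_base = trand_base, vth = vth, offset = offset,
         resp_amp = resp_amp, resp_period = resp_period,
         circ_amp = circ_amp, circ_period = circ_period,
         circ_shape = circ_shape),
    class = "sim_params")
}

#' Phenotype presets
#'
#' Parameter sets for the three modelled phenotypes: `normal` (balanced
#' autonomic modulation; T0 = 200, Tb = 200, ebpsf = 0.7), `hplsm`
#' (inherently slower clock, T0 = 500, otherwise as normal) and `snd`
#' (sinus node dysfunction; T0 = 200, Tb = 50, ebpsf = 1.8 — a
#' disproportionally strong block response to parasympathetic tone).
#'
#' @param name One of `"normal"`, `"hplsm"`, `"snd"`.
#' @return A [sim_params()].
#' @export
sim_preset <- function(name = c("normal", "hplsm", "snd")) {
  name <- match.arg(name)
  switch(name,
         normal = sim_params(t0 = 200, tb = 200, ebpsf = 0.7),
         hplsm  = sim_params(t0 = 500, tb = 200, ebpsf = 0.7),
         snd    = sim_params(t0 = 200, tb = 50, ebpsf = 1.8))
}

preset_diagnosis <- function(name) {
  c(normal = "BALANCED", hplsm = "HPLSM", snd = "SND")[[name]]
}

#' Vagal-tone waveform
#'
#' Dimensionless parasympathetic drive as a function of model time:
#' a constant floor, a respiratory oscillation
#' `resp_amp * (1 + sin(2 pi t / 4000))` (15 cycles/min), and a circadian
#' component `circ_amp * (1 - tanh(cos(2 pi t / P) * s))` that rises and
#' falls slowly over 24 h, peaking at `t = P / 2`.
#'
#' @param t Time(s) in ms from simulation start.
#' @param params A [sim_params()].
#' @return Vagal-tone level(s), bounded and continuous.
#' @export
vagal_tone <- function(t, params) {
  params$offset +
    params$resp_amp * (1 + sin(2 * pi * t / params$resp_period)) +
    params$circ_amp *
      (1 - tanh(cos(2 * pi * t / params$circ_period) * params$circ_shape))
}

#' Exit-block probability
#'
#' Zero below the vagal threshold; above it, rises linearly with slope
#' `ebpsf`, clamped to `[0, 1]`.
#'
#' @param vt Vagal-tone level(s).
#' @param params A [sim_params()].
#' @return Probability in `[0, 1]`.
#' @examples
#' block_probability(0.8, sim_preset("snd"))  # 1.8 * (0.8 - 0.6) = 0.36
#' @export
block_probability <- function(vt, params) {
  pmin(pmax(ifelse(vt < params$vth, 0, params$ebpsf * (vt - params$vth)), 0), 1)
}

#' Next internal-clock interval
#'
#' `Tint = T0 + vtdps * vagal_tone(t) + Trand * u`, with `u` uniform on
#' `[0, 1)` and `Trand` equal to `trand_base` after a conducted beat or
#' `tb` after a blocked one.
#'
#' @param t Current time (ms).
#' @param prev_blocked Was the previous internal beat blocked?
#' @param params A [sim_params()].
#' @param u Uniform draw; defaults to `runif(1)` from the current RNG
#'   stream (pass explicitly for deterministic checks).
#' @return Interval in ms.
#' @export
next_internal_interval <- function(t, prev_blocked, params, u = stats::runif(1)) {
  trand <- if (prev_blocked) params$tb else params$trand_base
  params$t0 + params$vtdps * vagal_tone(t, params) + trand * u
}

#' Simulate a rhythm with probabilistic exit block
#'
#' Iterates the internal clock from `start_time_ms`; each internal beat is
#' blocked with [block_probability()] evaluated at its own time. Conducted
#' RR intervals are the sums of consecutive internal intervals between
#' conducted beats, so no time is lost to blocks. A trailing run of
#' blocked beats at the end of the simulated span has no closing conducted
#' beat and contributes no conducted interval (it remains in the internal
#' log).
#'
#' Model time 0 is anchored to clock 14:00 by default, placing the
#' circadian vagal peak (at 12 h of model time) near 02:00 so that
#' block-rich rhythm falls inside the usual sleep hours.
#'
#' @param params A [sim_params()].
#' @param duration_ms Span to simulate (ms).
#' @param seed Optional integer seed for reproducibility.
#' @param start_time_ms Model time at which the recording starts (ms);
#'   sets the circadian phase.
#' @param anchor_clock Clock time corresponding to model time 0.
#' @param label Optional diagnosis attached to the conducted series.
#' @return Object of class `sim_result`: `series` (conducted
#'   [rr_series()]), `internal` (`data.frame(time, tint, blocked)`),
#'   `params`, `seed`, `start_time_ms`.
#' @export
simulate_rhythm <- function(params, duration_ms, seed = NULL,
                            start_time_ms = 0, anchor_clock = "14:00:00",
                            label = NULL) {
  stopifnot(duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  cap <- ceiling(duration_ms / params$t0) + 16L
  time <- numeric(cap)
  tint <- numeric(cap)
  blocked <- logical(cap)
  t <- start_time_ms
  end <- start_time_ms + duration_ms
  prev_blocked <- FALSE
  i <- 0L
  while (TRUE) {
    ti <- next_internal_interval(t, prev_blocked, params)
    t_new <- t + ti
    if (t_new > end) break
    i <- i + 1L
    if (i > cap) {  # defensive growth; t0 bounds make this rare
      time <- c(time, numeric(cap)); tint <- c(tint, numeric(cap))
      blocked <- c(blocked, logical(cap)); cap <- 2L * cap
    }
    b <- stats::runif(1) < block_probability(vagal_tone(t_new, params), params)
    time[i] <- t_new
    tint[i] <- ti
    blocked[i] <- b
    prev_blocked <- b
    t <- t_new
  }
  internal <- data.frame(time = time[seq_len(i)], tint = tint[seq_len(i)],
                         blocked = blocked[seq_len(i)])
  # conducted RR = accumulated internal intervals up to each conducted beat
  conducted_idx <- which(!internal$blocked)
  csum <- cumsum(internal$tint)
  rr <- diff(c(0, csum[conducted_idx]))
  anchor <- if (is.character(anchor_clock)) parse_clock(anchor_clock) else anchor_clock
  series <- rr_series(rr, start_clock = (anchor + start_time_ms / 1000) %% 86400,
                      label = label)
  structure(list(series = series, internal = internal, params = params,
                 seed = seed, start_time_ms = start_time_ms),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d internal beats, %d blocked (%.1f%%), %d conducted intervals\n",
              nrow(x$internal), sum(x$internal$blocked),
              100 * mean(x$internal$blocked), length(x$series$intervals)))
  invisible(x)
}

#' Generate a labelled synthetic cohort
#'
#' Simulates `n_per_class` recordings for each phenotype preset with
#' consecutive derived seeds (`seed`, `seed + 1`, ...), attaching the
#' diagnosis label to each conducted series. The default one-hour
#' recordings start at model time 12 h — the circadian vagal-tone peak,
#' clock ~02:00 — the regime in which the exit-block mechanism is active
#' and the three phenotypes express their characteristic beat-to-beat
#' patterns.
#'
#' @param n_per_class Recordings per diagnosis class.
#' @param duration_ms Recording length (ms; default 1 h).
#' @param seed Master seed; recording `i` of the cohort uses
#'   `seed + i - 1`.
#' @param start_time_ms Model time of recording onset (ms).
#' @return List of labelled [rr_series()] (class order BALANCED, HPLSM,
#'   SND), with the per-recording seed in attribute `"seed"` and the
#'   preset name in attribute `"preset"`.
#' @export
generate_labeled_cohort <- function(n_per_class = 3, duration_ms = 3600000,
                                    seed = 1, start_time_ms = 43200000) {
  stopifnot(n_per_class >= 1)
  out <- list()
  k <- 0L
  for (preset in c("normal", "hplsm", "snd")) {
    for (r in seq_len(n_per_class)) {
      rec_seed <- seed + k
      sim <- simulate_rhythm(sim_preset(preset), duration_ms, seed = rec_seed,
                             start_time_ms = start_time_ms,
                             label = preset_diagnosis(preset))
      s <- sim$series
      attr(s, "seed") <- rec_seed
      attr(s, "preset") <- preset
      out[[k + 1L]] <- s
      k <- k + 1L
    }
  }
  out
}
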