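flat_vagal <- function(level, preset = "normal") {
  # waveform collapsed to a constant so formulas can be checked exactly
  p <- sim_preset(preset)
  sim_params(t0 = p$t0, tb = p$tb, ebpsf = p$ebpsf,
             offset = level, resp_amp = 0, circ_amp = 0)
}

test_that("presets echo the published phenotype parameters", {
  normal <- sim_preset("normal")
  hplsm <- sim_preset("hplsm")
  snd <- sim_preset("snd")
  expect_equal(c(normal$t0, normal$tb, normal$ebpsf), c(200, 200, 0.7))
  expect_equal(hplsm$t0, 500)
  expect_equal(c(hplsm$tb, hplsm$ebpsf), c(200, 0.7))  # inherited
  expect_equal(c(snd$t0, snd$tb, snd$ebpsf), c(200, 50, 1.8))
  for (p in list(normal, hplsm, snd)) {
    expect_equal(p$vtdps, 400)
    expect_equal(p$vth, 0.6)
    expect_equal(p$trand_base, 40)
  }
  expect_error(sim_preset("dog"))
})

test_that("vagal tone is offset plus respiratory plus circadian terms", {
  p0 <- flat_vagal(0.08)
  expect_equal(vagal_tone(c(0, 123456, 7e7), p0), rep(0.08, 3))

  # respiratory component has a 4000 ms period: 15 cycles per minute
  p <- sim_preset("normal")
  pr <- sim_params(t0 = 200, tb = 200, ebpsf = 0.7, circ_amp = 0)
  t <- seq(0, 59999, by = 1)
  vt <- vagal_tone(t, pr)
  expect_equal(vagal_tone(t + 4000, pr), vt, tolerance = 1e-12)
  crossings <- sum(diff(vt > p$offset + pr$resp_amp) == 1)
  expect_equal(crossings, 15)

  # full waveform over 24 h stays positive and bounded
  vt24 <- vagal_tone(seq(0, 86400000, by = 60000), p)
  expect_gt(min(vt24), 0)
  expect_lt(max(vt24), 1.2)
})

test_that("block probability is a clamped threshold-linear function", {
  snd <- sim_preset("snd")
  normal <- sim_preset("normal")
  expect_equal(block_probability(0.5, snd), 0)
  expect_equal(block_probability(0.8, snd), 1.8 * 0.2)
  expect_equal(block_probability(0.8, normal), 0.7 * 0.2)
  expect_equal(block_probability(5, snd), 1)  # clamp
  # monotone in vagal tone and in the scale factor
  vt <- seq(0, 1.2, by = 0.01)
  expect_true(all(diff(block_probability(vt, snd)) >= 0))
  expect_true(all(block_probability(vt, snd) >= block_probability(vt, normal)))
})

test_that("internal intervals follow T0 + vtdps*vt + Trand*u", {
  p <- flat_vagal(0.5)
  expect_equal(next_internal_interval(0, FALSE, p, u = 0), 400)
  expect_equal(next_internal_interval(0, FALSE, p, u = 0.5), 420)
  # after a block the randomness span switches to Tb
  psnd <- flat_vagal(0.5, "snd")
  expect_equal(next_internal_interval(0, TRUE, psnd, u = 1), 400 + 50)
  expect_equal(next_internal_interval(0, FALSE, psnd, u = 1), 400 + 40)

  # Monte-Carlo against the uniform closed form: mean 420, support [400, 440)
  set.seed(81)
  draws <- replicate(10000, next_internal_interval(0, FALSE, p))
  expect_true(all(draws >= 400 & draws < 440))
  expect_equal(mean(draws), 420, tolerance = 0.5)
})

test_that("simulation conserves time and respects the no-block limits", {
  # ebpsf = 0: no block ever, conducted series equals the internal clock
  p0 <- sim_params(t0 = 200, tb = 200, ebpsf = 0)
  sim <- simulate_rhythm(p0, 600000, seed = 82, start_time_ms = 43200000)
  expect_equal(sum(sim$internal$blocked), 0)
  expect_equal(sim$series$intervals, sim$internal$tint)

  # threshold above the waveform maximum: SND preset degenerates likewise
  psnd <- sim_params(t0 = 200, tb = 50, ebpsf = 1.8, vth = 2)
  sim2 <- simulate_rhythm(psnd, 600000, seed = 83, start_time_ms = 43200000)
  expect_equal(sum(sim2$internal$blocked), 0)

  # conducted RR sums internal intervals exactly up to the last conducted beat
  sim3 <- simulate_rhythm(sim_preset("snd"), 1200000, seed = 84,
                          start_time_ms = 43200000)
  expect_gt(sum(sim3$internal$blocked), 0)
  last <- max(which(!sim3$internal$blocked))
  expect_equal(sum(sim3$series$intervals), sum(sim3$internal$tint[1:last]),
               tolerance = 1e-9)
  # each conducted interval spans one conducted beat plus preceding blocks
  expect_equal(length(sim3$series$intervals), sum(!sim3$internal$blocked))

  # reproducible per seed
  sim4 <- simulate_rhythm(sim_preset("snd"), 1200000, seed = 84,
                          start_time_ms = 43200000)
  expect_identical(sim4$series$intervals, sim3$series$intervals)
})

test_that("SND rhythm shows more pauses than the normal phenotype", {
  for (sd in 1:3) {
    snd <- simulate_rhythm(sim_preset("snd"), 3600000, seed = sd,
                           start_time_ms = 43200000)$series
    normal <- simulate_rhythm(sim_preset("normal"), 3600000, seed = sd,
                              start_time_ms = 43200000)$series
    expect_gt(basic_metrics(snd)$n_pauses_gt2,
              basic_metrics(normal)$n_pauses_gt2)
  }
})

test_that("labelled cohorts are reproducible and class-balanced", {
  coh <- generate_labeled_cohort(3, duration_ms = 300000, seed = 85)
  expect_length(coh, 9)
  labels <- sapply(coh, function(s) s$label)
  expect_equal(unname(table(labels)[diagnosis_levels()]), rep(3L, 3),
               ignore_attr = TRUE)
  seeds <- sapply(coh, attr, "seed")
  expect_equal(seeds, 85:93)

  coh2 <- generate_labeled_cohort(3, duration_ms = 300000, seed = 85)
  for (i in seq_along(coh)) {
    expect_identical(coh2[[i]]$intervals, coh[[i]]$intervals)
  }
})
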