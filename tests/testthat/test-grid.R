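test_that("grid geometry has one million 60-ms cells", {
  g <- grid_geometry()
  expect_equal(g$cell_edge, 60)
  expect_equal(g$axis_max, 6000)
  expect_equal(g$n_cells, (6000 / 60)^3)
  expect_equal(g$n_cells, 1000000L)
  expect_error(grid_geometry(cell_edge = 70), "multiple")
})

test_that("cell_index floors into cells with a half-open upper bound", {
  expect_equal(unname(cell_index(c(0, 0, 0))[1, ]), c(0L, 0L, 0L))
  # interval values as printed on an exit-block electrocardiogram
  expect_equal(unname(cell_index(c(660, 2633, 1336))[1, ]), c(11L, 43L, 22L))
  expect_true(all(is.na(cell_index(c(6000, 100, 100))[1, ])))
  expect_true(all(is.na(cell_index(c(100, -1, 100))[1, ])))
  expect_false(anyNA(cell_index(c(5999.9, 0, 3000))))
})

test_that("train_grid accumulates labelled triples per cell", {
  cohort <- list(
    rr_series(rep(600, 4), label = "BALANCED"),   # two triples, cell (10,10,10)
    rr_series(rep(900, 3), label = "HPLSM"),
    rr_series(rep(3000, 3), label = "SND"))
  m <- train_grid(cohort)
  key_b <- 10 + 100 * 10 + 10000 * 10
  expect_true(key_b %in% m$keys)
  expect_equal(unname(m$counts[match(key_b, m$keys), "BALANCED"]), 2)
  expect_equal(unname(m$class_totals), c(2, 1, 1))
  expect_equal(unname(m$outside), c(0, 0, 0))

  # missing classes are named in the error
  expect_error(train_grid(cohort[1]), "HPLSM, SND")
  expect_error(train_grid(list(rr_series(rep(600, 4)))), "label")
})

test_that("grid conservation: cell counts plus outside equal triples presented", {
  cohort <- generate_labeled_cohort(1, duration_ms = 300000, seed = 51)
  m <- train_grid(cohort)
  presented <- sapply(diagnosis_levels(), function(cl) {
    sum(sapply(cohort, function(s) {
      if (s$label == cl) max(length(s$intervals) - 2, 0) else 0
    }))
  })
  expect_equal(unname(m$class_totals + m$outside), unname(presented))
  expect_equal(unname(colSums(m$counts)), unname(m$class_totals))
  expect_true(all(m$counts >= 0))
})

test_that("cell labels use per-class normalised density", {
  # shared cell at 630 ms: BALANCED holds 10 of ~1000 triples, SND 5 of
  # ~100, so SND is denser there despite the smaller raw count
  balanced <- rr_series(c(rep(630, 12), rep(300, 994)), label = "BALANCED")
  snd <- rr_series(c(rep(630, 7), rep(3900, 101)), label = "SND")
  hp <- rr_series(rep(1200, 5), label = "HPLSM")
  m <- train_grid(list(balanced, snd, hp))
  shared <- c(630, 630, 630)
  expect_equal(classify_triples(m, shared), "SND")
  expect_equal(classify_triples(m, shared, normalize = FALSE), "BALANCED")
  # single-class cell and abstentions
  expect_equal(classify_triples(m, c(300, 300, 300)), "BALANCED")
  expect_equal(classify_triples(m, c(5000, 5000, 5000)), "NO_DECISION")
  expect_equal(classify_triples(m, c(6100, 100, 100)), "NO_DECISION")
})

test_that("rolling vote resolves interval diagnoses by plurality", {
  rv <- poincaregrid:::rolling_vote
  lv <- diagnosis_levels()
  # 5 intervals, 3 triples: middle interval sees all three votes
  expect_equal(rv(c("SND", "SND", "HPLSM"), 5, lv)[3], "SND")
  # abstentions are ignored in the plurality
  expect_equal(rv(c("NO_DECISION", "SND", "NO_DECISION"), 5, lv)[3], "SND")
  # all abstain
  expect_equal(unique(rv(rep("NO_DECISION", 3), 5, lv)), "NO_DECISION")
  # exact two-way tie falls back to the fixed class order
  expect_equal(rv(c("SND", "HPLSM"), 4, lv)[2], "HPLSM")
})

test_that("classify_series is unanimous on single-cluster recordings", {
  cohort <- list(rr_series(rep(600, 50), label = "BALANCED"),
                 rr_series(rep(1200, 50), label = "HPLSM"),
                 rr_series(rep(3000, 50), label = "SND"))
  m <- train_grid(cohort)
  res <- classify_series(m, rr_series(rep(1200, 30)))
  expect_equal(res$diagnosis, "HPLSM")
  expect_equal(unname(res$fractions["HPLSM"]), 1)
  expect_equal(sum(res$fractions), 1)

  # a recording entirely outside the training support abstains
  res2 <- classify_series(m, rr_series(rep(5500, 10)))
  expect_equal(res2$diagnosis, "NO_DECISION")
  expect_equal(unname(res2$fractions["NO_DECISION"]), 1)

  expect_error(classify_series(m, rr_series(c(600, 600))), "3 intervals")
})

test_that("confusion_matrix tabulates predicted rows by actual columns", {
  lv <- diagnosis_levels()
  actual <- rep(lv, each = 5)
  cm <- confusion_matrix(actual, actual)
  expect_equal(unname(diag(cm)), c(5, 5, 5))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  cm2 <- confusion_matrix(actual, rep("BALANCED", 15))
  expect_equal(unname(cm2["BALANCED", ]), c(5, 5, 5))
  expect_equal(unname(colSums(cm2)), c(5, 5, 5))

  expect_error(confusion_matrix(lv, lv[1:2]), "equal length")
})

test_that("grid model persistence round-trips classifications", {
  cohort <- generate_labeled_cohort(1, duration_ms = 300000, seed = 61)
  m <- train_grid(cohort)
  p <- withr::local_tempfile(fileext = ".json")
  write_grid_model(m, p)
  m2 <- read_grid_model(p)
  expect_equal(m2$keys, m$keys)
  expect_equal(unname(m2$class_totals), unname(m$class_totals))
  tr <- extract_triples(cohort[[3]])
  expect_equal(classify_triples(m2, tr), classify_triples(m, tr))
})
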