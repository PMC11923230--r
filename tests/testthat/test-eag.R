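mk_series <- function(stimuli, amplitudes, antenna = "a1") {
  data.frame(antenna_id = antenna,
             presentation_index = seq_along(stimuli),
             stimulus = stimuli, amplitude_mV = amplitudes,
             stringsAsFactors = FALSE)
}

test_that("first presentation of each test stimulus is dropped", {
  stim <- c("PAA", "PAA", "A", "B", "A", "PAA", "B", "A", "PAA")
  ser <- mk_series(stim, rep(1, length(stim)))
  out <- drop_first_responses(ser)
  # A first seen at 3, B at 4: those go; controls all stay
  expect_equal(out$presentation_index, c(1, 2, 5, 6, 7, 8, 9))
  expect_true(all(out$stimulus[out$presentation_index %in% c(1, 2, 6, 9)] == "PAA"))
  # stimulus at indices {5, 9, 13} keeps {9, 13}
  stim2 <- c("PAA", "PAA", "A", "A", "C", "A", "PAA", "A", "C", "A", "PAA",
             "A", "C")
  out2 <- drop_first_responses(mk_series(stim2, rep(1, 13)))
  expect_equal(out2$presentation_index[out2$stimulus == "C"], c(9, 13))
  # single-presentation stimulus vanishes with a warning
  expect_warning(
    out3 <- drop_first_responses(mk_series(c("PAA", "D", "PAA"), c(1, 1, 1))),
    "single presentation")
  expect_false("D" %in% out3$stimulus)
})

test_that("dropping firsts matches a group-by-minimum oracle", {
  set.seed(31)
  for (rep in 1:10) {
    stim <- c("PAA", sample(c("A", "B", "C", "PAA"), 25, replace = TRUE), "PAA")
    ser <- mk_series(stim, runif(length(stim), 0.5, 3))
    out <- suppressWarnings(drop_first_responses(ser))
    expect_drop <- unlist(lapply(setdiff(unique(stim), "PAA"), function(s)
      min(which(stim == s))))
    expect_equal(sort(out$presentation_index),
                 sort(setdiff(seq_along(stim), expect_drop)))
  }
})

test_that("control baseline interpolates linearly between anchor blocks", {
  flat <- mk_series(c("PAA", "A", "PAA", "A", "PAA"), c(2, 1, 2, 1, 2))
  bl <- control_baseline(flat)
  expect_equal(bl(1:5), rep(2, 5))
  two <- mk_series(c("PAA", rep("A", 9), "PAA"), c(4, rep(1, 9), 2))
  bl2 <- control_baseline(two)
  expect_equal(bl2(6), 3)
  expect_equal(bl2(1), 4)
  expect_equal(bl2(11), 2)
  # constant extension beyond the anchors
  expect_equal(bl2(0), 4)
  expect_equal(bl2(15), 2)
  # three anchor blocks of two presentations each: piecewise-linear through
  # block means at block mean indices
  stim3 <- c("PAA", "PAA", "A", "A", "PAA", "PAA", "A", "A", "PAA", "PAA")
  amp3 <- c(4.0, 3.8, 1, 1, 3.0, 2.8, 1, 1, 2.0, 1.8)
  bl3 <- control_baseline(mk_series(stim3, amp3))
  anchors_x <- c(1.5, 5.5, 9.5)
  anchors_y <- c(3.9, 2.9, 1.9)
  for (i in 1:10)
    expect_equal(bl3(i), approx(anchors_x, anchors_y, xout = i, rule = 2)$y)
  expect_error(control_baseline(mk_series(c("PAA", "A"), c(2, 1))[1, ]),
               "two control")
})

test_that("normalization divides by the local baseline", {
  ser <- mk_series(c("PAA", "A", "PAA"), c(2, 2, 2))
  norm <- eag_normalize(ser)
  expect_equal(norm$corrected_amplitude, rep(1, 3))
  expect_equal(norm$scaled_amplitude, rep(1, 3))
  # baseline decayed to half, raw response unchanged -> corrected doubles
  full <- mk_series(c("PAA", "A", "PAA"), c(2, 1, 2))
  half <- mk_series(c("PAA", "A", "PAA"), c(1, 1, 1))
  expect_equal(eag_normalize(half)$corrected_amplitude[2],
               2 * eag_normalize(full)$corrected_amplitude[2])
})

test_that("normalization cancels drift that is linear between anchors", {
  stim <- c("PAA", "A", "B", "A", "PAA", "B", "A", "B", "PAA")
  amp <- c(2, 1.5, 1.2, 1.5, 2, 1.2, 1.5, 1.2, 2)
  ser <- mk_series(stim, amp)
  drift <- seq(1, 0.4, length.out = length(stim))  # linear fatigue
  drifted <- ser
  drifted$amplitude_mV <- amp * drift
  expect_equal(eag_normalize(drifted)$corrected_amplitude,
               eag_normalize(ser)$corrected_amplitude, tolerance = 1e-12)
})

test_that("known stimulus ratios are recovered after normalization", {
  # no fatigue, no noise: corrected equals rho exactly on retained responses
  syn0 <- synth_eag(seed = 32, n_antennae = 1, k = 0, noise_sd = 0,
                    first_inflation = 2)
  norm0 <- eag_normalize(drop_first_responses(syn0$series))
  for (s in names(syn0$truth$rho)) {
    vals <- norm0$corrected_amplitude[norm0$stimulus == s]
    expect_equal(vals, rep(unname(syn0$truth$rho[s]), length(vals)),
                 tolerance = 1e-9)
  }
  # exponential fatigue with noise: per-antenna stimulus-mean ratios recover
  # the true rho ratios within 3 SE across antennae
  syn <- synth_eag(seed = 33, n_antennae = 9)
  norm <- eag_normalize(drop_first_responses(syn$series))
  rho <- syn$truth$rho
  per_ant <- tapply(norm$corrected_amplitude,
                    list(norm$antenna_id, norm$stimulus), mean)
  for (pair in list(c("McY", "air"), c("MvY", "solvent"), c("MvR", "McR"))) {
    ratios <- per_ant[, pair[1]] / per_ant[, pair[2]]
    se <- sd(ratios) / sqrt(length(ratios))
    expect_lt(abs(mean(ratios) - rho[pair[1]] / rho[pair[2]]), 3 * se)
  }
  # mean corrected amplitudes recover the true response ordering
  overall <- colMeans(per_ant[, names(rho)])
  expect_equal(order(overall), order(rho))
})
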