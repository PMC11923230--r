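cfg <- peak_filter_config()

mk_peak <- function(rt = 10, area = 2e5, hits = c("alpha-pinene", "x", "y"),
                    sample_id = "s1") {
  data.frame(sample_id = sample_id, rt_min = rt, area = area,
             hit1 = hits[1], hit2 = hits[2], hit3 = hits[3],
             stringsAsFactors = FALSE)
}

test_that("area filter drops sub-threshold peaks and keeps the boundary", {
  peaks <- rbind(mk_peak(area = 9.9e4), mk_peak(area = 1e5),
                 mk_peak(area = 5e5))
  kept <- filter_area(peaks, cfg)
  expect_equal(kept$area, c(1e5, 5e5))
  expect_error(filter_area(mk_peak(area = -1), cfg), "non-negative")
  set.seed(11)
  rnd <- mk_peak()[rep(1, 100), ]
  rnd$area <- runif(100, 1e4, 1e6)
  expect_equal(nrow(filter_area(rnd, cfg)), sum(rnd$area >= 1e5))
  expect_equal(filter_area(rnd, cfg)$area, rnd$area[rnd$area >= 1e5])
})

test_that("retention filter excludes peaks eluting strictly after the cutoff", {
  peaks <- rbind(mk_peak(rt = 30.01), mk_peak(rt = 30), mk_peak(rt = 12))
  expect_equal(filter_retention(peaks, cfg)$rt_min, c(30, 12))
  set.seed(12)
  rnd <- mk_peak()[rep(1, 80), ]
  rnd$rt_min <- runif(80, 0, 40)
  expect_equal(filter_retention(rnd, cfg)$rt_min,
               rnd$rt_min[rnd$rt_min <= 30])
})

test_that("blank matching removes peaks under the 5-fold criterion", {
  blank <- mk_peak(rt = 10.05, area = 1e5, hits = c("alpha-pinene", "", ""),
                   sample_id = "blank")
  below <- mk_peak(rt = 10.00, area = 4e5)
  above <- mk_peak(rt = 10.00, area = 6e5)
  res <- filter_blank_matched(rbind(below, above), blank, cfg)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$area, 4e5)
  expect_equal(res$removed$blank_area, 1e5)
  expect_equal(res$retained$area, 6e5)
  # boundary: exactly 5-fold is retained
  exact <- mk_peak(rt = 10.00, area = 5e5)
  expect_equal(nrow(filter_blank_matched(exact, blank, cfg)$removed), 0)
  expect_warning(out <- filter_blank_matched(below, blank[0, ], cfg),
                 "empty blank")
  expect_equal(nrow(out$retained), 1)
})

test_that("contaminant filter requires all three hits to be dirty", {
  dirty <- mk_peak(hits = c("hexamethylcyclotrisiloxane", "siloxane X",
                            "dibutyl phthalate"))
  partial <- mk_peak(hits = c("siloxane A", "siloxane B", "beta-myrcene"))
  expect_equal(nrow(filter_contaminants(dirty, cfg)), 0)
  expect_equal(nrow(filter_contaminants(partial, cfg)), 1)
})

test_that("full cascade equals the brute-force four-predicate oracle", {
  set.seed(13)
  for (rep in 1:25) {
    peaks <- random_peak_table(30)
    blanks <- random_peak_table(12, sample_id = "blank")
    keep <- oracle_cascade_keep(peaks, blanks, cfg)
    res <- filter_peaks(peaks, blanks, cfg)
    expect_equal(res$peaks[, 1:6], peaks[keep, , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(nrow(res$log), sum(!keep))
  }
})

test_that("Kovats index hits 100n at rungs and interpolates linearly", {
  ladder <- data.frame(carbon = c(8, 9, 10, 11, 12, 13),
                       rt_min = c(4, 7, 10.5, 14, 17.2, 20.1))
  expect_equal(kovats_index(ladder$rt_min, ladder), 100 * ladder$carbon)
  expect_equal(kovats_index((10.5 + 14) / 2, ladder), 1050)
  ladder13 <- data.frame(carbon = 12:14, rt_min = c(17.2, 20.1, 22.8))
  expect_equal(kovats_index(17.2 + 0.3 * (20.1 - 17.2), ladder13), 1230)
  # strictly increasing and continuous across a rung
  rts <- seq(4, 20.1, length.out = 200)
  ri <- kovats_index(rts, ladder)
  expect_true(all(diff(ri) > 0))
  expect_error(kovats_index(3.9, ladder), "span")
  expect_error(kovats_index(20.2, ladder), "span")
})

test_that("quantification converts area to ng/flower/hour via the curve", {
  curve <- data.frame(compound = "alpha-pinene", slope = 2e4, intercept = 1e4)
  em0 <- quantify_emissions(mk_peak(area = 1e4), curve, scaling = 48)
  expect_equal(em0$emission, 0)
  em1 <- quantify_emissions(mk_peak(area = 1e4 + 48 * 2e4), curve, scaling = 48)
  expect_equal(em1$emission, 1)
  em <- quantify_emissions(mk_peak(area = 5e5), curve, scaling = 48)
  expect_equal(em$emission, (5e5 - 1e4) / 2e4 / 48, tolerance = 1e-12)
  expect_equal(round(em$emission, 4), 0.5104)
  expect_warning(
    emc <- quantify_emissions(mk_peak(area = 5e3), curve, scaling = 48),
    "clipped")
  expect_equal(emc$emission, 0)
  expect_error(quantify_emissions(mk_peak(hits = c("nohit", "", "")), curve),
               "nohit")
  # surrogate routing for compounds without their own standard
  sur <- quantify_emissions(mk_peak(hits = c("myrtenol", "", ""), area = 5e5),
                            curve, scaling = 48,
                            surrogates = c(myrtenol = "alpha-pinene"))
  expect_equal(sur$emission, em$emission)
  expect_equal(sur$compound, "myrtenol")
})

test_that("totals sum compounds and fold change is a ratio of means", {
  expect_warning(expect_equal(total_emission(numeric(0)), 0), "no emission")
  expect_equal(total_emission(c(3, 2, 0.036)), 5.036)
  set.seed(14)
  x <- rexp(20)
  expect_equal(total_emission(x), sum(x))
  expect_true(total_emission(x) >= max(x))
  expect_equal(fold_change(c(2, 4), c(2, 4)), 1)
  expect_equal(round(fold_change(675.830, 291.169), 2), 2.32)
  expect_error(fold_change(1, c(-1, 1)), "zero")
})

test_that("quantified totals are linear in area above the intercept", {
  curve <- data.frame(compound = "alpha-pinene", slope = 2e4, intercept = 1e4)
  peaks <- rbind(mk_peak(area = 3e5), mk_peak(area = 7e5), mk_peak(area = 2e5))
  tot <- function(p) total_emission(quantify_emissions(p, curve)$emission)
  scaled <- peaks
  scaled$area <- 1e4 + 3 * (peaks$area - 1e4)
  expect_equal(tot(scaled), 3 * tot(peaks), tolerance = 1e-12)
})

test_that("Welch t test matches the hand-computed formulas", {
  res <- welch_t(1:3, 4:6)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(round(res$p, 4), 0.0213)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, 1:3), "at least two")
})
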