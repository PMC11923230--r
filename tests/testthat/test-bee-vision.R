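grid <- 300:700

test_that("replicate averaging is an idempotent pointwise mean", {
  base <- data.frame(line = "L", plant_id = "p1", flower_id = "f1",
                     wavelength_nm = grid, stringsAsFactors = FALSE)
  three_same <- rbind(cbind(base, reflectance = 0.3, replicate = 1),
                      cbind(base, reflectance = 0.3, replicate = 2),
                      cbind(base, reflectance = 0.3, replicate = 3))
  avg <- average_spectra(three_same)
  expect_equal(avg$reflectance, rep(0.3, length(grid)))
  consts <- do.call(rbind, lapply(c(0.2, 0.4, 0.6), function(v)
    cbind(base, reflectance = v)))
  expect_equal(average_spectra(consts)$reflectance, rep(0.4, length(grid)))
})

test_that("hierarchical averaging weights flowers equally, not replicates", {
  # flower f1 has 3 replicates at 0.3, flower f2 one replicate at 0.6:
  # flower means (0.3, 0.6) average to 0.45, not the pooled 0.375
  base <- data.frame(line = "L", plant_id = "p1", wavelength_nm = grid,
                     stringsAsFactors = FALSE)
  spectra <- rbind(cbind(base, flower_id = "f1", reflectance = 0.3),
                   cbind(base, flower_id = "f1", reflectance = 0.3),
                   cbind(base, flower_id = "f1", reflectance = 0.3),
                   cbind(base, flower_id = "f2", reflectance = 0.6))
  expect_equal(average_spectra(spectra)$reflectance, rep(0.45, length(grid)))
  set.seed(21)
  rnd <- rbind(cbind(base, flower_id = "f1", reflectance = runif(length(grid))),
               cbind(base, flower_id = "f2", reflectance = runif(length(grid))),
               cbind(base, flower_id = "f3", reflectance = runif(length(grid))))
  avg <- average_spectra(rnd)
  manual <- (rnd$reflectance[rnd$flower_id == "f1"] +
             rnd$reflectance[rnd$flower_id == "f2"] +
             rnd$reflectance[rnd$flower_id == "f3"]) / 3
  expect_equal(avg$reflectance[order(avg$wavelength_nm)],
               manual[order(grid)])
  bad <- rnd
  bad$wavelength_nm[1] <- 299.5
  expect_error(average_spectra(bad), "grid")
})

test_that("receptor template peaks at lambda_max with unit height", {
  for (lm in c(344, 436, 544)) {
    s <- receptor_template(lm, grid)
    expect_equal(max(s), 1)
    expect_lte(abs(grid[which.max(s)] - lm), 1)
    # monotone decline on the long-wavelength limb
    tail_region <- s[grid > lm + 30]
    expect_true(all(diff(tail_region) < 0))
    expect_true(all(s >= 0))
  }
  expect_error(receptor_template(250, grid), "300")
  # the optional beta band adds a short-wavelength shoulder without
  # disturbing the normalization
  sb <- receptor_template(544, grid, beta = TRUE)
  s0 <- receptor_template(544, grid)
  expect_equal(max(sb), 1)
  expect_gt(sb[grid == 360], s0[grid == 360])
})

test_that("quantum catch implements von Kries adaptation and transduction", {
  recs <- bee_receptors(grid)
  bg <- green_leaf_background(grid)
  self <- quantum_catch(bg, recs, bg)
  expect_equal(self$q, rep(1, 3))
  expect_equal(self$E, rep(0.5, 3))
  dbl <- quantum_catch(2 * bg, recs, bg)
  expect_equal(dbl$q, rep(2, 3))
  expect_equal(dbl$E, rep(2 / 3, 3))
  # raw catch equals the brute-force Riemann sum on a 5-nm grid
  g5 <- seq(300, 700, by = 5)
  set.seed(22)
  refl <- runif(length(g5))
  sens <- receptor_template(436, g5)
  illum <- runif(length(g5), 0.5, 1.5)
  qc <- quantum_catch(refl, sens, rep(0.2, length(g5)), illum, g5)
  brute <- 0
  for (i in seq_along(g5)) brute <- brute + refl[i] * sens[i] * illum[i] * 5
  expect_equal(qc$Q, brute)
})

test_that("hexagon coordinates follow the two axis formulas", {
  centre <- hexagon_coords(0.5, 0.5, 0.5)
  expect_equal(unlist(centre), c(x = 0, y = 0, contrast = 0))
  pt <- hexagon_coords(0.2, 0.5, 0.8)
  expect_equal(pt$x, sqrt(3) / 2 * 0.6)
  expect_equal(round(pt$x, 4), 0.5196)
  expect_equal(pt$y, 0)
  expect_equal(pt$contrast, pt$x)
  # swapping UV and green negates x, preserves y and contrast
  sw <- hexagon_coords(0.8, 0.5, 0.2)
  expect_equal(sw$x, -pt$x)
  expect_equal(sw$y, pt$y)
  expect_equal(sw$contrast, pt$contrast)
  expect_error(hexagon_coords(0, 0.5, 0.5), "inside")
})

test_that("any spectrum proportional to the background maps to the centre", {
  recs <- bee_receptors(grid)
  bg <- green_leaf_background(grid)
  for (c_scale in c(0.25, 1, 3)) {
    pt <- hexagon_point(c_scale * bg, bg, recs)
    expect_equal(pt$x, 0, tolerance = 1e-12)
    expect_equal(pt$y, 0, tolerance = 1e-12)
  }
})

test_that("yellow-like spectra contrast more against green than red-like", {
  syn <- synth_spectra(seed = 23)
  avg <- average_spectra(syn$spectra)
  recs <- bee_receptors(grid)
  bg <- syn$background$reflectance
  con <- sapply(c("yellow", "red"), function(l)
    hexagon_point(avg$reflectance[avg$line == l], bg, recs)$contrast)
  expect_gt(con["yellow"], con["red"])
})
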