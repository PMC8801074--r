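test_that("lot panel has the prescribed composition and calibration", {
  panel <- generateLotPanel(7, 4, seed = 1)
  expect_s4_class(panel, "LotPanel")
  expect_length(panel, 11)
  expect_equal(sum(riskClass(panel) == "Low"), 7)
  expect_equal(sum(riskClass(panel) == "High"), 4)
  g <- growthRateTrue(panel)
  # preset extremes: 9.0 / 1.5 = 6.0-fold spread, beyond the 5.8 the design
  # requires; class ranges overlap so growth alone cannot classify
  expect_equal(max(g) / min(g), 6.0)
  expect_gt(max(g[riskClass(panel) == "Low"]),
            min(g[riskClass(panel) == "High"]) - 1.5)
  f <- cfseProlifFrac(panel)
  expect_true(all(f[riskClass(panel) == "Low"] <= 0.05))
  expect_true(all(f[riskClass(panel) == "High"] >= 0.15))
  # degenerate single-lot panel
  p1 <- generateLotPanel(1, 0, seed = 99)
  expect_length(p1, 1)
  expect_lte(cfseProlifFrac(p1)[[1]], 0.05)
  expect_error(generateLotPanel(-1, 4), "n_low")
  expect_error(generateLotPanel(0, 0), "at least one lot")
})

test_that("schedule arithmetic matches the imaging design", {
  expect_length(scheduleTimes(), 22)
  expect_equal(scheduleTimes()[1], 12)
  expect_equal(scheduleTimes()[22], 138)
  expect_error(scheduleTimes(12, 139, 6), "divisible")
})

test_that("top-quartile calibration inverts the closed form", {
  mu <- calibrateAreaMu(7000, 0.65)
  # analytic top-quartile mean of lognormal(mu, sigma)
  topq <- function(mu, s) exp(mu + s^2 / 2) * pnorm(s - qnorm(0.75)) / 0.25
  expect_equal(topq(mu, 0.65), 7000, tolerance = 1e-9)
  # Monte-Carlo oracle: mean of the top 25% of 1e6 draws, within 0.5%
  set.seed(7)
  x <- rlnorm(1e6, mu, 0.65)
  mc <- mean(x[x > quantile(x, 0.75)])
  expect_equal(mc, 7000, tolerance = 0.005)
  # sigma -> 0 degenerates to the point mass
  expect_equal(calibrateAreaMu(5000, 1e-8), log(5000), tolerance = 1e-6)
  # the two class calibrations sit at the printed 86% ratio
  mu_h <- calibrateAreaMu(6000, 0.45)
  expect_equal(topq(mu_h, 0.45) / topq(mu, 0.65), 6000 / 7000,
               tolerance = 1e-9)
  expect_error(calibrateAreaMu(-1, 0.5), "positive")
  expect_error(calibrateAreaMu(7000, 0), "positive")
})

test_that("time course follows the exponential growth law", {
  panel <- generateLotPanel(1, 0, seed = 3)
  panel@lots$growth_rate_true <- 4
  cells <- simulateTimecourse(panel, n_wells = 1, n0_cells = 500,
                              well_cv = 0, seed = 3)
  cnt <- table(cells$time_h)
  expect_length(cnt, 22)
  expect_equal(unname(cnt[["12"]]), 500)
  expect_equal(unname(cnt[["138"]]), 2000)
  # no growth, no well noise: constant counts
  panel@lots$growth_rate_true <- 1
  c2 <- simulateTimecourse(panel, n_wells = 1, n0_cells = 300, well_cv = 0,
                           seed = 3)
  expect_true(all(table(c2$time_h) == 300))
  expect_error(simulateTimecourse(panel, n_wells = 0), "n_wells")
})

test_that("generator is deterministic and substream-stable", {
  panel <- generateLotPanel(2, 1, seed = 5)
  a <- simulateTimecourse(panel, n_wells = 2, n0_cells = 50, seed = 5)
  b <- simulateTimecourse(panel, n_wells = 2, n0_cells = 50, seed = 5)
  expect_identical(a, b)
  # adding lots must not perturb existing lots
  p1 <- generateLotPanel(7, 4, seed = 11)
  p2 <- generateLotPanel(7, 6, seed = 11)
  expect_identical(cfseProlifFrac(p1), cfseProlifFrac(p2)[1:11])
  expect_identical(areaMu(p1), areaMu(p2)[1:11, ])
  c1 <- simulateTimecourse(p1, n_wells = 1, n0_cells = 40, seed = 11,
                           lots = "lot01")
  c2 <- simulateTimecourse(p2, n_wells = 1, n0_cells = 40, seed = 11,
                           lots = "lot01")
  expect_identical(c1, c2)
  cf1 <- simulateCFSE(p1, "lot02", n_events = 500, seed = 11)
  cf2 <- simulateCFSE(p2, "lot02", n_events = 500, seed = 11)
  expect_identical(cf1, cf2)
})

test_that("class signal: High-risk area SD is narrower early on", {
  panel <- generateLotPanel(7, 4, seed = 2)
  cells <- simulateTimecourse(panel, n_wells = 1, n0_cells = 400, seed = 2)
  sm <- aggregateFrames(cells, min_cells = 50)
  risk <- riskClass(panel)
  for (tt in c(12, 36)) {
    sub <- sm[sm$time_h == tt, ]
    lo <- mean(sub$sd_area[risk[sub$lot] == "Low"])
    hi <- mean(sub$sd_area[risk[sub$lot] == "High"])
    expect_gt(lo, hi)
  }
})

test_that("CFSE mixture matches its distributional oracle", {
  # spec-level fact: fraction below the 2.4 valley at pi = 0.5 equals the
  # mixture CDF there, 0.4959171
  panel <- generateLotPanel(1, 0, seed = 4)
  panel@lots$cfse_prolif_frac <- 0.5
  cf <- simulateCFSE(panel, "lot01", n_events = 1e6, seed = 4)
  expect_equal(mean(cf$intensity < 2.4), 0.4959171, tolerance = 0.002)
  # pi = 0: everything in the unproliferated peak
  panel@lots$cfse_prolif_frac <- 0
  cf0 <- simulateCFSE(panel, "lot01", n_events = 1e5, seed = 4)
  expect_true(all(cf0$intensity > 2.2))
  expect_error(simulateCFSE(panel, "lot01", n_events = 50), ">= 100")
})

test_that("rendered frames conserve cells and areas", {
  # empty frame -> empty mask
  img0 <- renderImage(data.frame(area = numeric()), image_px = 64,
                      pixel_size_um = 2, seed = 1)
  expect_true(all(img0@truthMask == 0))
  # count conservation at zero noise
  cells <- data.frame(area = rep(2000, 10), aspect_ratio = 1.3)
  img <- renderImage(cells, image_px = 256, pixel_size_um = 2,
                     noise_sd = 0, seed = 2)
  expect_equal(max(img@truthMask), 10)
  expect_equal(img@nDropped, 0)
  expect_identical(sort(unique(as.integer(img@truthMask))), 0:10)
  # prescribed area survives rasterization: 5000 um^2 at 2 um/px ~ 1250 px
  img1 <- renderImage(data.frame(area = 5000, aspect_ratio = 1.2),
                      image_px = 128, pixel_size_um = 2, seed = 3)
  expect_equal(sum(img1@truthMask == 1), 1250, tolerance = 0.02)
  # determinism
  img2 <- renderImage(cells, image_px = 256, pixel_size_um = 2,
                      noise_sd = 0, seed = 2)
  expect_identical(img@pixels, img2@pixels)
})
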