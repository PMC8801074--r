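make_cells <- function(n, area = 1000) {
  as.data.frame(matrix(area, n, 16,
                       dimnames = list(NULL, descriptorNames())))
}

test_that("frame aggregation yields the 32 mean/SD parameters", {
  f <- aggregateFrame(make_cells(300))
  expect_equal(f$n_cells, 300)
  expect_false(f$qc_flag)
  vals <- f[!(names(f) %in% c("n_cells", "qc_flag"))]
  expect_length(vals, 32)
  expect_equal(f$mean_area, 1000)
  expect_equal(f$sd_area, 0)
  # hand-computed sample SD (n - 1), cross-checked by the two-pass oracle
  cells <- make_cells(5)
  cells$area <- c(100, 200, 300, 400, 500)
  g <- aggregateFrame(cells, min_cells = 3)
  expect_equal(g$mean_area, 300)
  expect_equal(g$sd_area, 158.1138830, tolerance = 1e-9)
  expect_equal(g$sd_area, bf_sd(cells$area))
  # degenerate inputs are flagged, not raised
  e <- aggregateFrame(make_cells(0))
  expect_true(e$qc_flag)
  expect_true(is.na(e$mean_area))
  expect_true(aggregateFrame(make_cells(100))$qc_flag)
})

test_that("aggregation is permutation-invariant and matches the SD oracle", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    cells <- as.data.frame(matrix(rlnorm(n * 16, 7, 0.5), n, 16,
                                  dimnames = list(NULL, descriptorNames())))
    a <- aggregateFrame(cells, min_cells = 10)
    b <- aggregateFrame(cells[sample(n), ], min_cells = 10)
    expect_equal(a, b)
    expect_equal(a$sd_perimeter, bf_sd(cells$perimeter))
  }
})

test_that("profile assembly gives 32 x 22 matrices and imputes gaps", {
  panel <- generateLotPanel(1, 1, seed = 6)
  cells <- simulateTimecourse(panel, n_wells = 1, n0_cells = 250, seed = 6)
  sm <- aggregateFrames(cells, min_cells = 50)
  prof <- assembleProfiles(sm)
  expect_s4_class(prof, "MorphProfileSet")
  expect_equal(dim(prof), c(704, 2)) # 32 params x 22 times, 2 samples
  expect_false(any(SummarizedExperiment::assay(prof, "imputed")))
  # drop one interior frame: imputed value is the mean of its neighbours
  sm2 <- sm[!(sm$lot == "lot01" & sm$time_h == 48), ]
  prof2 <- assembleProfiles(sm2)
  m <- SummarizedExperiment::assay(prof2, "profile")
  im <- SummarizedExperiment::assay(prof2, "imputed")
  i48 <- which(rownames(m) == "mean_area_t48")
  s1 <- grep("^lot01", colnames(m))
  expect_true(im[i48, s1])
  expect_equal(m[i48, s1],
               (m[which(rownames(m) == "mean_area_t42"), s1] +
                m[which(rownames(m) == "mean_area_t54"), s1]) / 2)
  # > 20% missing frames rejects the sample
  sm3 <- sm[!(sm$lot == "lot01" & sm$time_h %in% c(18, 30, 48, 66, 90, 120)), ]
  expect_warning(prof3 <- assembleProfiles(sm3), "rejecting")
  expect_equal(ncol(prof3), 1)
  expect_match(S4Vectors::metadata(prof3)$rejected, "lot01")
})

test_that("parameter modes partition the 32 rows", {
  panel <- generateLotPanel(1, 1, seed = 6)
  cells <- simulateTimecourse(panel, n_wells = 1, n0_cells = 250, seed = 6)
  prof <- assembleProfiles(aggregateFrames(cells, min_cells = 50))
  sd_only <- subsetParameters(prof, "only_SD")
  no_sd <- subsetParameters(prof, "without_SD")
  expect_equal(nrow(sd_only), 16 * 22)
  expect_equal(nrow(no_sd), 16 * 22)
  expect_true(all(SummarizedExperiment::rowData(sd_only)$stat == "sd"))
  expect_true(all(SummarizedExperiment::rowData(no_sd)$stat == "mean"))
  expect_setequal(c(rownames(sd_only), rownames(no_sd)), rownames(prof))
  expect_identical(subsetParameters(prof, "mean+SD"), prof)
  expect_error(subsetParameters(prof, "bogus"))
  expect_error(subsetParameters(sd_only, "without_SD"), "already subset")
})

test_that("time windows truncate columns as scheduled", {
  panel <- generateLotPanel(1, 0, seed = 6)
  cells <- simulateTimecourse(panel, n_wells = 1, n0_cells = 250, seed = 6)
  prof <- assembleProfiles(aggregateFrames(cells, min_cells = 50))
  expect_equal(nrow(windowProfile(prof, 138)), 32 * 22)
  expect_equal(nrow(windowProfile(prof, 96)), 32 * 15) # (96-12)/6 + 1
  expect_equal(nrow(windowProfile(prof, 12)), 32)
  # window(window(p, a), b) = window(p, min(a, b))
  w1 <- windowProfile(windowProfile(prof, 96), 48)
  w2 <- windowProfile(prof, 48)
  expect_equal(SummarizedExperiment::assay(w1, "profile"),
               SummarizedExperiment::assay(w2, "profile"))
  expect_error(windowProfile(prof, 6), "before the first")
})

test_that("FOV splitting yields 4 conserving pseudo-samples per well", {
  panel <- generateLotPanel(2, 1, seed = 8)
  cells <- simulateTimecourse(panel, n_wells = 3, n0_cells = 500, seed = 8)
  sp <- splitFOVs(cells)
  expect_setequal(unique(sp$fov), c("f1", "f2", "f3", "f4"))
  # conservation: quadrant counts sum to the frame count
  byf <- sp[, .N, by = .(lot, well, time_h)]
  byq <- sp[, .N, by = .(lot, well, time_h, fov)][
    , .(N = sum(N)), by = .(lot, well, time_h)]
  expect_equal(byf$N, byq$N)
  # uniform positions: ~ balanced quadrants at 2000 cells
  one <- sp[lot == "lot03" & well == "w1" & time_h == 138]
  expect_gt(nrow(one), 1000)
  q <- table(one$fov)
  expect_true(all(abs(q / nrow(one) - 0.25) < 0.05))
  # assignment consistent across time: boundaries are fixed
  expect_true(all(sp[x_um < 1000 & y_um < 1000, fov] == "f1"))
  # 11 lots x 3 wells x 4 FOVs = 132 classification samples
  panel11 <- generateLotPanel(7, 4, seed = 8)
  cells11 <- simulateTimecourse(panel11, n_wells = 3, n0_cells = 60,
                                seed = 8)
  sm <- aggregateFrames(splitFOVs(cells11),
                        by = c("lot", "well", "fov", "time_h"),
                        min_cells = 5)
  prof <- assembleProfiles(sm)
  expect_equal(ncol(prof), 132)
})
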