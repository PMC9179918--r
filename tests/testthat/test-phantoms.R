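test_that("SPGR signal matches the closed form and its limits", {
  # frozen value from an independent evaluation of the SPGR equation
  expect_equal(simulateSpgrSignal(1000, 1200, 15, 15), 69.78262850290578,
               tolerance = 1e-12)
  expect_equal(
    simulateSpgrSignal(1000, 1200, 15, STUDY_FLIP_ANGLES),
    c(33.28739208, 66.91288965, 78.65215150, 69.78262850, 50.02211429,
      29.11663910),
    tolerance = 1e-8)
  # saturation: TR >> T1 and a 90 degree pulse recover M0
  expect_equal(simulateSpgrSignal(1000, 10, 1e5, 90), 1000,
               tolerance = 1e-9)
  # vanishing excitation gives vanishing signal
  expect_lt(simulateSpgrSignal(5000, 800, 20, 1e-6), 1e-3)
  expect_equal(simulateSpgrSignal(0, 1200, 15, STUDY_FLIP_ANGLES),
               rep(0, 6))
  expect_error(simulateSpgrSignal(1000, -5, 15, 10), "T1")
  expect_error(simulateSpgrSignal(1000, 1200, 0, 10), "TR")
})

test_that("multi-echo signal matches the mono-exponential model", {
  expect_equal(simulateMultiechoSignal(500, 30, 0), 500)
  expect_equal(simulateMultiechoSignal(500, 30, 30), 500 / exp(1))
  # frozen vector from independent formula evaluation on the 16
  # study echo times, S0 = 500, T2 = 30 ms
  expect_equal(
    simulateMultiechoSignal(500, 30, STUDY_ECHO_TIMES),
    c(456.96559264, 436.13046566, 416.24530631, 397.26680125,
      379.15361203, 361.86628498, 345.36716532, 329.62031510,
      314.59143496, 300.24778941, 286.55813549, 273.49265477,
      261.02288838, 249.12167501, 237.76309175, 226.92239764),
    tolerance = 1e-8)
  s <- simulateMultiechoSignal(500, 30, STUDY_ECHO_TIMES)
  expect_true(all(diff(s) < 0) && all(s > 0))
  expect_error(simulateMultiechoSignal(500, 0, 10), "T2")
})

test_that("cartilage phantom is constructive and deterministic", {
  spec <- cartilagePhantomSpec(shape = c(8L, 8L, 6L))
  ph <- makeCartilagePhantom(spec)
  # noiseless: every voxel stack equals the closed-form signal of its
  # region
  r1 <- spec@regions[1, ]
  expect_equal(as.numeric(voxelData(ph$vfa)[3, 3, 1, ]),
               simulateSpgrSignal(r1$M0, r1$T1, spec@tr,
                                  spec@flipAngles))
  expect_equal(as.numeric(voxelData(ph$me)[5, 2, 1, ]),
               simulateMultiechoSignal(r1$M0, r1$T2, spec@echoTimes))
  # regions with distinct T2 differ at the first echo
  lab <- voxelData(ph$labelmap)
  me1 <- voxelData(ph$me)[, , , 1]
  expect_gt(abs(mean(me1[lab == 1]) - mean(me1[lab == 2])), 1)
  # identical spec (incl. seed) => bit-identical output with noise
  specN <- cartilagePhantomSpec(shape = c(8L, 8L, 6L), noiseSigma = 10,
                                seed = 11L)
  expect_identical(makeCartilagePhantom(specN), makeCartilagePhantom(specN))
  expect_error(makeCartilagePhantom(
    cartilagePhantomSpec(regions = data.frame(label = integer(0),
                                              T1 = numeric(0),
                                              T2 = numeric(0),
                                              M0 = numeric(0)))),
    "region")
})

test_that("Rician noise biases the mean signal upward", {
  # magnitude noise adds a positive bias at finite SNR; check on
  # repeated draws of the same phantom voxel population
  spec <- cartilagePhantomSpec(shape = c(12L, 12L, 8L),
                               regions = data.frame(label = 1L, T1 = 1200,
                                                    T2 = 30, M0 = 1000),
                               noiseSigma = 10, noiseModel = "rician",
                               seed = 5L)
  ph <- makeCartilagePhantom(spec)
  noiseless <- simulateSpgrSignal(1000, 1200, 15, spec@flipAngles)[1]
  # first flip angle has the weakest signal, hence the largest bias
  drawn <- mean(voxelData(ph$vfa)[, , , 1])   # 1152 independent draws
  expect_gt(drawn, noiseless)
})

test_that("trabecular plate lattice carries exact analytic truths", {
  tb <- makeTrabecularPhantom(trabecularPhantomSpec())
  expect_equal(tb$truth@bvtv, 0.2)
  tb4 <- makeTrabecularPhantom(trabecularPhantomSpec(thickness = 4L))
  expect_equal(tb4$truth@tbTh, 0.4)
  expect_equal(tb4$truth@tbSp, 0.6)
  expect_equal(tb4$truth@tbN, 1.0)
  # TbN identity holds exactly on the analytic truth
  expect_identical(tb4$truth@tbN * tb4$truth@tbTh / tb4$truth@bvtv, 1)
  expect_error(trabecularPhantomSpec(thickness = 10L, period = 10L),
               "thickness")
})

test_that("thresholded random field hits its target fill fraction", {
  spec <- trabecularPhantomSpec(shape = c(128L, 128L, 128L),
                                lattice = "thresholded_random_field",
                                fillFraction = 0.3, seed = 2L)
  tb <- makeTrabecularPhantom(spec)
  frac <- sum(voxelData(tb$binary)) / prod(dim(voxelData(tb$binary)))
  expect_lt(abs(frac - 0.30), 0.01)
  expect_equal(tb$truth@bvtv, frac)
})

test_that("score datasets are balanced, seeded, and carry planted effects", {
  d <- makeOrdinalScoreDataset(scoreSimSpec(seed = 9L))
  expect_equal(nrow(d), 54L)   # 3 groups x 3 times x n = 6
  expect_true(all(table(d$group, d$time_days) == 6L))
  expect_identical(d, makeOrdinalScoreDataset(scoreSimSpec(seed = 9L)))
  d2 <- makeOrdinalScoreDataset(scoreSimSpec(nPerCell = 2L))
  expect_equal(nrow(d2), 2L * 3L * 3L)
  # planted location shift in one group dominates the pooled trimmed
  # mean in nearly all seeds
  eff <- matrix(0, 3, 3); eff[2, ] <- 1.5
  hits <- vapply(1:500, function(s) {
    dd <- makeOrdinalScoreDataset(scoreSimSpec(cellEffects = eff,
                                               noise = "normal",
                                               seed = s))
    tms <- vapply(split(dd$value, dd$group),
                  function(x) trimmedMeanStats(x, 0.2)$tmean, numeric(1))
    names(which.max(tms)) == "CGH"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
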