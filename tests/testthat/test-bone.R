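test_that("binarisation is idempotent on clean lattices and symmetric
          under contrast inversion", {
  tb <- makeTrabecularPhantom(trabecularPhantomSpec())
  voi <- array(TRUE, dim(voxelData(tb$binary)))
  bin <- binarizeTrabeculae(VolumeGrid(voxelData(tb$binary) + 0, 0.1), voi)
  frac_diff <- mean(voxelData(bin) != voxelData(tb$binary))
  expect_lte(frac_diff, 0.01)
  inv <- binarizeTrabeculae(VolumeGrid(-(voxelData(tb$binary) + 0), 0.1),
                            voi, invert = TRUE)
  expect_identical(voxelData(inv), voxelData(bin))
  expect_error(binarizeTrabeculae(VolumeGrid(array(1, c(4, 4, 4))),
                                  array(TRUE, c(4, 4, 4))),
               "constant")
})

test_that("blurred plates are re-binarised to the true bone fraction", {
  tb <- makeTrabecularPhantom(trabecularPhantomSpec(blurFwhm = 0.1))
  bin <- binarizeTrabeculae(tb$gray, tb$voi)
  expect_lt(abs(boneVolumeFraction(bin, tb$voi) - 0.2), 0.02)
})

test_that("bone volume fraction is an exact voxel-count ratio", {
  voi <- array(TRUE, c(6, 6, 6))
  expect_equal(boneVolumeFraction(array(TRUE, c(6, 6, 6)), voi), 1.0)
  expect_equal(boneVolumeFraction(array(FALSE, c(6, 6, 6)), voi), 0.0)
  set.seed(2)
  b <- array(runif(216) > 0.5, c(6, 6, 6))
  expect_equal(boneVolumeFraction(b, voi), sum(b) / 216)
  expect_error(boneVolumeFraction(b, array(FALSE, c(6, 6, 6))), "empty")
  # monotonicity: adding a bone voxel never decreases BV/TV
  b2 <- b; b2[which(!b2)[1]] <- TRUE
  expect_gte(boneVolumeFraction(b2, voi), boneVolumeFraction(b, voi))
})

test_that("plate lattices reproduce analytic Tb.Th, Tb.Sp and TbN", {
  tb <- makeTrabecularPhantom(trabecularPhantomSpec(thickness = 4L))
  th <- as.numeric(trabecularThickness(tb$binary, voi = tb$voi))
  sp <- as.numeric(trabecularSpacing(tb$binary, voi = tb$voi))
  expect_lte(abs(th - 0.4), 0.1)
  expect_lte(abs(sp - 0.6), 0.1)
  bv <- boneVolumeFraction(tb$binary, tb$voi)
  tbn <- trabecularNumber(bv, th)
  expect_equal(tbn * th, bv, tolerance = 1e-14)   # identity by construction
  expect_lt(abs(tbn - tb$truth@tbN) / tb$truth@tbN, 0.15)
  expect_error(trabecularNumber(0.2, 0), "tbTh")
  expect_equal(trabecularNumber(0, 0.4), 0)
  expect_error(trabecularThickness(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("rod thickness converges to the rod diameter with
          resolution", {
  est <- vapply(c(0.2, 0.1, 0.05), function(spc) {
    w <- round(0.6 / spc)                 # 0.6 mm square rod
    n <- round(6 / spc / 2) * 2
    rod <- array(FALSE, c(n, n, n))
    lo <- n / 2 - w / 2 + 1
    rod[lo:(lo + w - 1), lo:(lo + w - 1), ] <- TRUE
    as.numeric(trabecularThickness(rod, spacing = rep(spc, 3)))
  }, numeric(1))
  expect_lte(abs(est[1] - 0.6), 0.2 + 1e-9)
  expect_lte(abs(est[2] - 0.6), 0.1 + 1e-9)
  expect_lte(abs(est[3] - 0.6), 0.05 + 1e-9)
})

test_that("biomarkers are stable under whole-voxel translations", {
  tb <- makeTrabecularPhantom(trabecularPhantomSpec())
  bin <- voxelData(tb$binary)
  voi <- voxelData(tb$voi)
  ref <- c(boneVolumeFraction(bin, voi),
           as.numeric(trabecularThickness(bin, voi = voi,
                                          spacing = rep(0.1, 3))),
           as.numeric(trabecularSpacing(bin, voi = voi,
                                        spacing = rep(0.1, 3))))
  # circular shift along x (periodic direction) by 3 voxels
  shifted <- bin[c(4:48, 1:3), , ]
  shf <- c(boneVolumeFraction(shifted, voi),
           as.numeric(trabecularThickness(shifted, voi = voi,
                                          spacing = rep(0.1, 3))),
           as.numeric(trabecularSpacing(shifted, voi = voi,
                                        spacing = rep(0.1, 3))))
  expect_true(all(abs(shf - ref) / ref < 0.01))
})

test_that("box-counting dimensions recover known structures", {
  # filled square slice: area mode ~ plane, boundary mode ~ perimeter
  sq <- array(TRUE, c(128, 128, 1))
  expect_lt(abs(fractalDimension2D(sq) - 2.0), 0.05)
  expect_lt(abs(fractalDimension2D(sq, mode = "boundary") - 1.0), 0.05)
  # a straight line is one-dimensional
  ln <- array(FALSE, c(64, 64, 1)); ln[, 10, 1] <- TRUE
  expect_lt(abs(fractalDimension2D(ln) - 1.0), 0.05)
  # exact self-similar fixture at 4 subdivisions
  carp <- sierpinskiCarpet(4)
  expect_equal(sum(carp), 8^4)
  vol <- array(carp, c(dim(carp), 1))
  expect_lt(abs(fractalDimension2D(vol) - log(8) / log(3)), 0.05)
  # under-determined scale ladders are an error
  expect_error(fractalDimension3D(array(TRUE, c(5, 5, 5))), "scales")
  expect_error(fractalDimension3D(array(FALSE, c(64, 64, 64))), "empty")
})
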