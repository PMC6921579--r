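blockObject <- function(arr, ...) {
  vol <- makeVolume(arr)
  objs <- detectObjects(vol, minSize = 1, ...)
  list(vol = vol, obj = objs[[1]])
}

test_that("projections collapse the right axis with max-intensity values", {
  arr <- array(0, dim = c(8, 8, 4))
  arr[2:4, 3:5, 2:3] <- 30
  arr[3, 4, 3] <- 90
  b <- blockObject(arr)
  xy <- projectObject(b$obj, b$vol, "XY")
  expect_equal(nrow(xy@pixels), 9)          # 3 x 3 square
  expect_setequal(unique(xy@pixels[, "u"]), 2:4)
  expect_setequal(unique(xy@pixels[, "v"]), 1:3)
  expect_equal(max(xy@intensities), 90)
  expect_equal(xy@vScale, 1)

  yz <- projectObject(b$obj, b$vol, "YZ")
  expect_equal(nrow(yz@pixels), 6)          # 3 y-rows x 2 z-slices
  expect_equal(yz@vScale, 62.5 / 25)
  expect_equal(nrow(projectObject(b$obj, b$vol, "YZ",
                                  physicalAspect = FALSE)@pixels), 6)
})

test_that("single-voxel and diagonal objects project to the expected masks", {
  arr <- array(0, dim = c(8, 8, 4)); arr[3, 5, 2] <- 50
  b <- blockObject(arr)
  expect_equal(nrow(projectObject(b$obj, b$vol, "XY")@pixels), 1)
  expect_equal(nrow(projectObject(b$obj, b$vol, "YZ")@pixels), 1)

  arr2 <- array(0, dim = c(8, 8, 4))
  for (i in 1:5) arr2[i, i, 1] <- 50
  b2 <- blockObject(arr2)
  xy <- projectObject(b2$obj, b2$vol, "XY")
  expect_equal(nrow(xy@pixels), 5)
  expect_true(all(xy@pixels[, "u"] == xy@pixels[, "v"]))
})

test_that("hull of the 4 corner pixels of a 10x10 square spans 9x9", {
  s <- convexHullShape(makeArea(cbind(c(0, 9, 0, 9), c(0, 0, 9, 9))))
  expect_equal(hullArea(s), 81)
  expect_equal(hullPerimeter(s), 36)
  expect_equal(circularity(s), pi / 4, tolerance = 1e-12)
})

test_that("degenerate masks are padded to keep the perimeter positive", {
  one <- convexHullShape(makeArea(cbind(3, 4)))
  expect_equal(hullArea(one), 1)
  expect_equal(hullPerimeter(one), 4)

  line <- convexHullShape(makeArea(cbind(0:4, rep(2, 5))))
  expect_gt(hullArea(line), 0)
  expect_equal(hullArea(line), 5)           # 5 x 1 strip of padded pixels
  expect_equal(hullPerimeter(line), 12)
})

test_that("hull area and perimeter match the gift-wrapping oracle", {
  set.seed(301)
  for (rep in 1:6) {
    px <- unique(cbind(sample(0:30, 50, TRUE), sample(0:30, 50, TRUE)))
    s <- convexHullShape(makeArea(px))
    ref <- oracleHull(cbind(px[, 1], px[, 2]))
    expect_lt(abs(hullArea(s) - ref$S), 1e-9)
    expect_lt(abs(hullPerimeter(s) - ref$P), 1e-9)
    expect_gte(hullArea(s), nrow(px) * 0 + 1e-12)  # positive
  }
})

test_that("circularity follows the closed forms for disk, square, rectangle", {
  disk <- convexHullShape(makeArea(diskMask(64, 160)))
  expect_equal(circularity(disk), 1, tolerance = 0.02)

  expect_equal(circularity(1, 4), pi / 4)
  expect_equal(circularity(400, 404), 4 * pi * 400 / 404^2)
  expect_error(circularity(10, 0), "positive")
})

test_that("refining a rasterized disk drives circularity towards 1", {
  ca <- vapply(c(8, 16, 32, 64),
               function(r) circularity(convexHullShape(makeArea(diskMask(r)))),
               numeric(1))
  expect_true(all(diff(ca) > 0))
  expect_lt(max(abs(ca - 1)), 0.05)
})

test_that("circularity is invariant under rotation and translation of the mask", {
  set.seed(302)
  px <- unique(cbind(sample(0:20, 40, TRUE), sample(0:20, 40, TRUE)))
  ca <- circularity(convexHullShape(makeArea(px)))
  rot <- cbind(px[, 2], 20 - px[, 1])           # 90 degree rotation
  expect_equal(circularity(convexHullShape(makeArea(rot))), ca,
               tolerance = 1e-9)
  shift <- cbind(px[, 1] + 7, px[, 2] + 3)
  expect_equal(circularity(convexHullShape(makeArea(shift))), ca,
               tolerance = 1e-9)
})

test_that("minimum circularity picks the flatter projection", {
  # a slab: wide and flat in XY, thin in z -> YZ hull is elongated
  arr <- array(0, dim = c(16, 16, 6))
  arr[3:10, 3:10, 3] <- 50
  b <- blockObject(arr)
  mc <- minCircularity(b$obj, b$vol)
  xy <- circularity(convexHullShape(projectObject(b$obj, b$vol, "XY")))
  yz <- circularity(convexHullShape(projectObject(b$obj, b$vol, "YZ")))
  expect_equal(mc$circularity, min(xy, yz))
  expect_equal(mc$plane, c("XY", "YZ")[which.min(c(xy, yz))])
})

test_that("integrated density sums projected grey values", {
  a <- makeArea(cbind(rep(0:2, 3), rep(0:2, each = 3)),
                intensities = rep(10, 9))
  expect_equal(integratedDensity(a), 90)
  expect_equal(integratedDensity(makeArea(cbind(4, 4), intensities = 55)),
               55)
  set.seed(303)
  px <- unique(cbind(sample(0:9, 20, TRUE), sample(0:9, 20, TRUE)))
  vals <- runif(nrow(px), 0, 100)
  expect_equal(integratedDensity(makeArea(px, intensities = vals)),
               sum(vals))
})

test_that("shape tables have one row per object and plane with a min flag", {
  arr <- array(0, dim = c(12, 12, 5)); arr[2:5, 2:5, 2:3] <- 60
  vol <- makeVolume(arr)
  res <- summarizeSample(vol, sampleId = "s")
  tab <- shapeTable(res, vol)
  expect_equal(nrow(tab), 2 * length(detectedObjects(res)))
  expect_equal(sum(tab$is_min_circularity), length(detectedObjects(res)))
  expect_true(all(tab$circularity > 0))
})
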