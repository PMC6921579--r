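test_that("a bright block is detected with its exact descriptors", {
  arr <- array(0, dim = c(8, 8, 5)); arr[2:4, 3:5, 2:4] <- 50
  objs <- detectObjects(makeVolume(arr))
  expect_length(objs, 1)
  expect_equal(nVoxels(objs[[1]]), 27L)
  expect_equal(meanIntensity(objs[[1]]), 50)
  expect_equal(unname(centroid(objs[[1]])), c(3, 2, 2))
  expect_equal(boundingBox(objs[[1]]), c(2L, 1L, 1L, 5L, 4L, 4L))
})

test_that("the detection threshold is strict and defaults to 20 grey levels", {
  arr <- array(0, dim = c(8, 8, 5)); arr[2:4, 3:5, 2:4] <- 10
  expect_length(detectObjects(makeVolume(arr)), 0)
  arr[2:4, 3:5, 2:4] <- 20          # exactly at threshold: excluded
  expect_length(detectObjects(makeVolume(arr)), 0)
  arr[2:4, 3:5, 2:4] <- 20.5
  expect_length(detectObjects(makeVolume(arr)), 1)
})

test_that("the minimum object size filter is inclusive at 20 voxels", {
  arr <- array(0, dim = c(12, 12, 6))
  arr[2:4, 2:4, 2:4] <- 50          # 27 voxels: retained
  arr[8:9, 8:9, 4:5] <- 50          # 8 voxels: removed
  objs <- detectObjects(makeVolume(arr))
  expect_length(objs, 1)
  expect_equal(nVoxels(objs[[1]]), 27L)

  arr2 <- array(0, dim = c(12, 12, 6))
  arr2[2:6, 2:5, 2] <- 50           # exactly 20 voxels in one slice
  expect_length(detectObjects(makeVolume(arr2)), 1)
  arr2[6, 5, 2] <- 0                # 19 voxels
  expect_length(detectObjects(makeVolume(arr2)), 0)
})

test_that("components match a brute-force flood fill on random volumes", {
  set.seed(201)
  for (rep in 1:6) {
    conn <- if (rep %% 2 == 0) 6L else 26L
    fg <- array(runif(12 * 12 * 8) < 0.25, dim = c(12, 12, 8))
    arr <- array(0, dim = dim(fg)); arr[fg] <- 50
    objs <- detectObjects(makeVolume(arr), threshold = 20, minSize = 1,
                          connectivity = conn)
    ref <- oracleFloodFill(fg, conn)
    expect_equal(length(objs), max(ref))
    # identical partition: each object's voxels carry one oracle label,
    # and all labels are accounted for
    seen <- integer(0)
    for (o in objs) {
      v <- voxels(o)
      labs <- unique(ref[cbind(v[, "y"] + 1, v[, "x"] + 1, v[, "z"] + 1)])
      expect_length(labs, 1)
      expect_equal(nVoxels(o), sum(ref == labs))
      seen <- c(seen, labs)
    }
    expect_setequal(seen, seq_len(max(ref)))
  }
})

test_that("foreground voxels are covered exactly once (disjoint and complete)", {
  set.seed(202)
  arr <- array(ifelse(runif(10 * 10 * 6) < 0.3, 50, 0), dim = c(10, 10, 6))
  objs <- detectObjects(makeVolume(arr), minSize = 1)
  tot <- do.call(rbind, lapply(objs, voxels))
  expect_equal(nrow(tot), sum(arr > 20))
  expect_equal(nrow(unique(tot)), nrow(tot))
})

test_that("raising the threshold never increases the count of fixed-intensity objects", {
  # disjoint blocks, each of a single grey value, so components cannot
  # split as the threshold rises
  arr <- array(0, dim = c(14, 14, 6))
  arr[2:3, 2:3, 1:2] <- 30
  arr[6:7, 6:7, 2:3] <- 60
  arr[10:11, 2:3, 4:5] <- 90
  arr[2:3, 10:11, 5:6] <- 30
  vol <- makeVolume(arr)
  counts <- vapply(c(10, 45, 70, 100),
                   function(th) length(detectObjects(vol, th, minSize = 1)),
                   integer(1))
  expect_equal(counts, c(4L, 2L, 1L, 0L))
  expect_true(all(diff(counts) <= 0))
})

test_that("labels are deterministic in raster order of the minimum voxel index", {
  arr <- array(0, dim = c(10, 10, 4))
  arr[7:9, 7:9, 2:4] <- 40          # later in raster order
  arr[1:3, 1:3, 1:3] <- 50          # starts at voxel (0, 0, 0)
  objs <- detectObjects(makeVolume(arr), minSize = 1)
  expect_equal(objectLabel(objs[[1]]), 1L)
  expect_equal(voxels(objs[[1]])[1, ], c(x = 0L, y = 0L, z = 0L))
  expect_equal(meanIntensity(objs[[1]]), 50)
  expect_equal(meanIntensity(objs[[2]]), 40)
})

test_that("total biospeckle intensity is the sum of object means and is additive", {
  arr <- array(0, dim = c(10, 10, 4))
  arr[1:3, 1:3, 1:3] <- 30
  arr[7:9, 7:9, 2:4] <- 50
  objs <- detectObjects(makeVolume(arr), minSize = 1)
  expect_equal(totalBiospeckleIntensity(objs), 80)
  expect_equal(totalBiospeckleIntensity(list()), 0)
  expect_equal(totalBiospeckleIntensity(objs[1]), 30)
  expect_equal(totalBiospeckleIntensity(c(objs, objs)),
               2 * totalBiospeckleIntensity(objs))
})

test_that("an empty volume summarises to zero without error", {
  vol <- makeVolume(array(0, dim = c(6, 6, 3)))
  expect_length(detectObjects(vol), 0)
  res <- summarizeSample(vol, sampleId = "empty")
  expect_equal(totalBiospeckleIntensity(res), 0)
  expect_equal(nrow(objectTable(res)), 0)
})

test_that("sample summaries carry metadata, parameters and object rows", {
  arr <- array(0, dim = c(10, 10, 4)); arr[2:5, 2:6, 2:3] <- 60
  res <- summarizeSample(makeVolume(arr), bspimConfig(),
                         sampleId = "s1", timePointH = 2,
                         treatment = "PEITC", group = "plant_feeder")
  expect_s4_class(res, "SampleResult")
  expect_equal(sampleId(res), "s1")
  expect_equal(res@parameters$intensity_threshold, 20)
  tab <- objectTable(res)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_voxels, 40)
  expect_equal(tab$mean_intensity, 60)
})
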