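test_that("volume and mask NIfTI round-trips preserve values and geometry", {
    set.seed(BASE_SEED)
    arr <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
    vg <- volumeGrid(arr, spacing = c(1.6, 1.6, 2.0), origin = c(-10, 5, 2))
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeVolume(vg, f)
    back <- readVolume(f)
    expect_equal(voxels(back), arr, tolerance = 1e-12)
    expect_equal(spacing(back), c(1.6, 1.6, 2.0))
    expect_equal(origin(back), c(-10, 5, 2), tolerance = 1e-5)

    labs <- array(sample(0:3, 120, replace = TRUE), dim = c(4, 5, 6))
    lm <- labelMask(labs, spacing = c(1.6, 1.6, 2.0), origin = c(1, 2, 3))
    g <- withr::local_tempfile(fileext = ".nii.gz")
    writeLabelMask(lm, g)
    backM <- readLabelMask(g)
    expect_identical(maskArray(backM), maskArray(lm))  # bit-exact integers
    expect_equal(spacing(backM), spacing(lm))
})

test_that("readVolume validates inputs and rejects DICOM series", {
    expect_error(readVolume(tempfile()), "not found")
    expect_error(readVolume("x.nii", format = "dicom"), "not supported")
})

test_that("rescale is the stored-value affine map and rejects slope 0", {
    expect_identical(applyRescale(100, 1, 0), 100)
    expect_identical(applyRescale(100, 2, 5), 205)
    a <- array(1:8, c(2, 2, 2))
    expect_equal(applyRescale(a, 0.5, 1), a * 0.5 + 1)
    expect_error(applyRescale(100, 0), "nonzero")
})

test_that("decay correction follows the half-life law", {
    expect_equal(decayCorrectActivity(100, 109.77, 109.77), 50)
    expect_equal(decayCorrectActivity(100, 0, 109.77), 100)
    # frozen from high-precision evaluation of 5e7 * 2^(-60/109.77)
    expect_equal(decayCorrectActivity(5.0e7, 60, 109.77), 34231645.98,
                 tolerance = 1e-8)
    expect_error(decayCorrectActivity(100, -1), ">= 0")
    expect_error(decayCorrectActivity(100, 10, 0), "positive")
})

test_that("decay correction is multiplicative over elapsed time", {
    set.seed(BASE_SEED)
    for (i in 1:25) {
        a <- runif(1, 1, 1e8)
        t1 <- runif(1, 0, 300); t2 <- runif(1, 0, 300)
        hl <- runif(1, 1, 200)
        expect_equal(decayCorrectActivity(a, t1 + t2, hl),
                     decayCorrectActivity(decayCorrectActivity(a, t1, hl),
                                          t2, hl),
                     tolerance = 1e-12)
    }
})

test_that("ROI extraction returns planted values in lexicographic order", {
    arr <- array(0, c(4, 4, 4))
    labs <- array(0L, c(4, 4, 4))
    labs[2:3, 2:3, 2:3] <- 3L           # 8-voxel cube labeled 3
    planted <- c(11, 12, 13, 14, 15, 16, 17, 18)
    arr[which(labs == 3L)] <- planted
    vg <- volumeGrid(arr)
    lm <- labelMask(labs)
    roi <- extractRoiVoxels(vg, lm, 3)
    expect_equal(roi$count, 8L)
    expect_equal(roi$values, planted)   # which() order = x fastest
    expect_true(all(diff(roi$index) > 0))
    expect_error(extractRoiVoxels(vg, lm, 7), "absent")
})

test_that("ROI extraction over all labels partitions the labeled voxels", {
    set.seed(BASE_SEED)
    labs <- array(sample(0:4, 6 * 5 * 7, replace = TRUE), dim = c(6, 5, 7))
    vg <- volumeGrid(array(rnorm(6 * 5 * 7), c(6, 5, 7)))
    lm <- labelMask(labs)
    counts <- vapply(1:4, function(l)
        extractRoiVoxels(vg, lm, l)$count, integer(1))
    expect_identical(sum(counts), sum(labs > 0L))
    idx <- unlist(lapply(1:4, function(l) extractRoiVoxels(vg, lm, l)$index))
    expect_identical(sort(idx), which(labs > 0L))
})

test_that("misaligned masks are rejected", {
    vg <- volumeGrid(array(0, c(4, 4, 4)))
    expect_error(checkAlignment(vg, labelMask(array(0L, c(4, 4, 5)))),
                 "shape")
    expect_error(checkAlignment(vg, labelMask(array(0L, c(4, 4, 4)),
                                              spacing = c(1, 1, 1))),
                 "spacing")
    full <- labelMask(array(1L, c(4, 4, 4)))
    roi <- extractRoiVoxels(vg, full, 1)
    expect_equal(roi$count, 64L)
})

test_that("acquisition metadata validates and decays the injected dose", {
    meta <- acquisitionMeta(5.36e7, 0, 60, bodyMass = 7e4)
    expect_equal(uptakeMinutes(meta), 60)
    expect_equal(injectedAtScan(meta),
                 decayCorrectActivity(5.36e7, 60, 109.77))
    expect_error(acquisitionMeta(-1, 0, 60, bodyMass = 7e4), "positive")
    expect_error(acquisitionMeta(5e7, 60, 0, bodyMass = 7e4), "precede")
})

test_that("label tables are read and validated", {
    f <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(label = 1:2, muscle_name = c("a", "b"),
                         side = c("dominant", "non_dominant"),
                         segment = c("thigh", "lower_leg")),
              f, row.names = FALSE)
    tab <- readLabelTable(f)
    expect_identical(tab$label, 1:2)
    bad <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(label = 1, muscle_name = "a", side = "left",
                         segment = "thigh"), bad, row.names = FALSE)
    expect_error(readLabelTable(bad), "side")
})
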