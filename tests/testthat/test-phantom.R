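test_that("ellipsoid masks match the analytic volume and validate bounds", {
    # fine 1 mm grid: voxelized ball volume within 2% of (4/3) pi r^3
    m <- ellipsoidMask(c(24L, 24L, 24L), spacing = c(1, 1, 1),
                       center = c(12, 12, 12), semiAxes = c(10, 10, 10))
    vol <- sum(maskArray(m) > 0L) * 1     # mm^3
    expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
    expect_error(ellipsoidMask(c(10L, 10L, 10L), center = c(8, 8, 10),
                               semiAxes = c(0, 3, 3)), "> 0")
    expect_error(ellipsoidMask(c(10L, 10L, 10L), spacing = c(1, 1, 1),
                               center = c(9, 5, 5), semiAxes = c(3, 3, 3)),
                 "bounds")
})

test_that("mirrored placement preserves voxel counts; mirroring is an involution", {
    m <- ellipsoidMask(c(40L, 20L, 20L), spacing = c(1, 1, 1),
                       center = c(12, 10, 10), semiAxes = c(8, 6, 6))
    mm <- mirrorMask(m)
    expect_equal(sum(maskArray(mm) > 0L), sum(maskArray(m) > 0L))
    expect_identical(maskArray(mirrorMask(mm)), maskArray(m))
    vg <- volumeGrid(array(rnorm(8), c(2, 2, 2)))
    expect_identical(voxels(mirrorMask(mirrorMask(vg))), voxels(vg))
})

test_that("gamma background has the requested moments and is seeded", {
    mask <- labelMask(array(1L, c(50L, 50L, 40L)))
    v1 <- sampleBackground(mask, shape = 4, scale = 25, seed = BASE_SEED)
    v2 <- sampleBackground(mask, shape = 4, scale = 25, seed = BASE_SEED)
    expect_identical(voxels(v1), voxels(v2))
    x <- voxels(v1)[maskArray(mask) == 1L]
    expect_lt(abs(mean(x) - 100) / 100, 0.01)          # mean = k * theta
    expect_lt(abs(sampleSkewness(x) - 1), 0.05)        # skew = 2/sqrt(k)
    expect_error(sampleBackground(mask, shape = 0, scale = 1), "> 0")
    # zero outside the ROI
    part <- labelMask(array(c(1L, 0L), c(10L, 10L, 10L)))
    vp <- sampleBackground(part, shape = 2, scale = 1, seed = 1L)
    expect_true(all(voxels(vp)[maskArray(part) == 0L] == 0))
})

test_that("hot-cluster injection is seeded, bounded and recoverable", {
    mask <- ellipsoidMask(c(32L, 32L, 26L), center = c(25.6, 25.6, 26),
                          semiAxes = c(15, 15, 15))
    bg <- sampleBackground(mask, shape = 16, scale = 1, seed = BASE_SEED)
    same1 <- injectHotClusters(bg, mask, 1L, 2L, 6, 3, seed = 7L)
    same2 <- injectHotClusters(bg, mask, 1L, 2L, 6, 3, seed = 7L)
    expect_identical(same1$blobs, same2$blobs)
    none <- injectHotClusters(bg, mask, 1L, 0L, 6, 3, seed = 7L)
    expect_identical(voxels(none$volume), voxels(bg))
    expect_error(injectHotClusters(bg, mask, 1L, 1L, 100, 3, seed = 1L),
                 "half-extent")
    expect_error(injectHotClusters(bg, mask, 1L, 1L, 6, 1, seed = 1L),
                 "> 1")

    # hot voxels land inside the true blob in >= 80% of cases
    hits <- vapply(1:10, function(s) {
        ph <- blobPhantom(seed = BASE_SEED + s)
        roiVox <- extractRoiVoxels(ph$volume, ph$mask, 1L)
        cls <- classifyHot(roiVox$values, 0.05)
        mean(roiVox$index[cls$hot] %in% ph$blob)
    }, numeric(1))
    expect_true(all(hits >= 0.8))
})

test_that("FWHM smoothing has the stated kernel width and conserves mass", {
    expect_equal(fwhmToSigma(3), 1.2740, tolerance = 1e-4)
    expect_equal(fwhmToSigma(3), 3 / (2 * sqrt(2 * log(2))))

    set.seed(BASE_SEED)
    vg <- volumeGrid(array(rnorm(20^3), c(20, 20, 20)))
    expect_identical(voxels(smoothFWHM(vg, 0)), voxels(vg))   # identity
    cv <- volumeGrid(array(5, c(12, 12, 12)))
    expect_equal(voxels(smoothFWHM(cv, 3)), voxels(cv),
                 tolerance = 1e-12)                           # constant fixed
    # interior-supported mass is preserved through the unit-mass kernel
    sp <- array(0, c(24, 24, 24))
    sp[10:14, 10:14, 10:14] <- rgamma(125, 2)
    vs <- volumeGrid(sp, spacing = c(1.6, 1.6, 2.0))
    expect_equal(sum(voxels(smoothFWHM(vs, 3))), sum(sp),
                 tolerance = 1e-6)
    expect_error(smoothFWHM(vg, -1), ">= 0")

    # smoothing an impulse spreads it with the per-axis voxel sigma
    imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
    sm <- voxels(smoothFWHM(volumeGrid(imp, spacing = c(1.6, 1.6, 2.0)), 3))
    profX <- sm[, 11, 11]; profZ <- sm[11, 11, ]
    sdX <- sqrt(sum(profX * (seq_len(21) - 11)^2) / sum(profX))
    sdZ <- sqrt(sum(profZ * (seq_len(21) - 11)^2) / sum(profZ))
    expect_equal(sdX, fwhmToSigma(3) / 1.6, tolerance = 0.02)
    expect_equal(sdZ, fwhmToSigma(3) / 2.0, tolerance = 0.02)
})

test_that("paired studies are seeded and encode the target SI exactly", {
    s1 <- makePairedStudy(smallPairSpec(42, seed = BASE_SEED))
    s2 <- makePairedStudy(smallPairSpec(42, seed = BASE_SEED))
    expect_identical(voxels(s1$dominant$volume), voxels(s2$dominant$volume))
    expect_identical(voxels(s1$nonDominant$volume),
                     voxels(s2$nonDominant$volume))

    gt <- s1$groundTruth$perMuscle
    expect_equal(symmetryIndex(gt$trueMeanConcDom, gt$trueMeanConcNonDom),
                 42, tolerance = 1e-9)
    expect_error(makePairedStudy(smallPairSpec(250, seed = 1L)),
                 "targetSI")
})

test_that("measured SI recovers the generated asymmetry after smoothing", {
    for (target in c(0, 42)) {
        si <- vapply(1:3, function(s) {
            measuredSI(makePairedStudy(
                smallPairSpec(target, seed = BASE_SEED + s)))
        }, numeric(1))
        expect_true(all(abs(si - target) <= 3))
    }
})

test_that("default phantom spec realizes three paper-scale muscles", {
    spec <- defaultPhantomSpec(seed = BASE_SEED)
    study <- makePairedStudy(spec)
    expect_setequal(unique(study$labelTable$segment),
                    c("pelvis", "thigh", "lower_leg"))
    counts <- vapply(1:3, function(l)
        extractRoiVoxels(study$dominant$volume, study$dominant$mask,
                         l)$count, integer(1))
    expect_true(all(counts > 2000))       # thousands of voxels per muscle
    suvD <- voxelwiseSUV(study$dominant$volume, study$meta)
    skews <- vapply(1:3, function(l)
        sampleSkewness(extractRoiVoxels(suvD, study$dominant$mask,
                                        l)$values), numeric(1))
    expect_true(all(skews > 0))           # right-skewed uptake throughout
})
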