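test_that("hot classification picks round(fraction*N) top voxels", {
    set.seed(BASE_SEED)
    v <- sample(seq_len(20))              # 20 distinct values
    cls <- classifyHot(v)
    expect_equal(cls$m, 1L)
    expect_identical(which(cls$hot), which.max(v))
    expect_false(cls$tiesBroken)

    # all equal, N = 40: two hot voxels, lowest indices, flagged as ties
    cls <- classifyHot(rep(1, 40))
    expect_equal(cls$m, 2L)
    expect_identical(which(cls$hot), 1:2)
    expect_true(cls$tiesBroken)

    # at least one hot voxel even for tiny ROIs
    expect_equal(classifyHot(c(3, 1))$m, 1L)
    expect_error(classifyHot(numeric(0)), "empty")
    expect_error(classifyHot(1:5, fraction = 1), "\\(0, 1\\)")
})

test_that("hot classification is invariant under increasing transforms", {
    set.seed(BASE_SEED)
    for (i in 1:20) {
        v <- rgamma(80, 2)
        a <- classifyHot(v)$hot
        expect_identical(classifyHot(exp(v))$hot, a)
        expect_identical(classifyHot(rank(v, ties.method = "first"))$hot, a)
    }
})

test_that("NHN counting matches trivial configurations", {
    roi <- array(TRUE, c(3, 3, 3))
    hot <- array(FALSE, c(3, 3, 3)); hot[2, 2, 2] <- TRUE
    nhn <- countHotNeighbors(hot, roi)
    expect_equal(nhn[2, 2, 2], 0L)        # isolated hot voxel
    expect_equal(sum(nhn), 6L)            # its 6 cold face-neighbors see it

    hotAll <- array(TRUE, c(3, 3, 3))     # fully-hot ROI: center saturates
    expect_equal(countHotNeighbors(hotAll, roi)[2, 2, 2], 6L)

    expect_error(countHotNeighbors(array(TRUE, c(2, 2, 2)),
                                   array(FALSE, c(2, 2, 2))),
                 "inside the ROI")
})

test_that("NHN excludes neighbors outside the ROI", {
    roi <- array(FALSE, c(4, 1, 1)); roi[2:3, 1, 1] <- TRUE
    hot <- array(FALSE, c(4, 1, 1)); hot[2, 1, 1] <- TRUE
    nhn <- countHotNeighbors(hot, roi)
    expect_equal(nhn[3, 1, 1], 1L)
    expect_equal(nhn[1, 1, 1], 0L)        # outside ROI: no NHN assigned
})

test_that("the 2 x 2 x 10 worked example yields cluster index 1/3", {
    dims <- c(2L, 2L, 10L)
    roi <- array(TRUE, dims)
    v <- array(0, dims)
    v[1, 1, 5] <- 10; v[1, 1, 6] <- 9     # the two hot voxels (m = 2)
    vg <- volumeGrid(v)
    lm <- labelMask(array(1L, dims))
    ca <- clusterAnalysis(vg, lm, 1L)
    expect_equal(ca$m, 2L)
    expect_equal(ca$meanNhnHot, 1)        # each hot voxel touches the other
    expect_equal(ca$meanNhnCold, 6 / 38)  # 6 hot-cold adjacencies / 38 cold
    expect_equal(ca$clusterIndex, 1 / 3, tolerance = 1e-12)
    # cross-check against the all-pairs oracle
    hot <- array(FALSE, dims); hot[1, 1, 5:6] <- TRUE
    expect_identical(countHotNeighbors(hot, roi), oracleNHN(hot, roi))
})

test_that("single hot voxel forces index 0; edge identities hold", {
    set.seed(BASE_SEED)
    for (i in 1:20) {
        dims <- sample(4:10, 3, replace = TRUE)
        roi <- array(runif(prod(dims)) < 0.7, dims)
        if (sum(roi) < 10) next
        vals <- rnorm(sum(roi))
        cls <- classifyHot(vals, fraction = 0.15)
        hot <- array(FALSE, dims); hot[which(roi)[cls$hot]] <- TRUE
        nhn <- countHotNeighbors(hot, roi)
        adj <- oracleAdjacency(hot, roi)
        expect_identical(sum(nhn[hot]), 2L * adj$hotHot)
        expect_identical(sum(nhn[roi & !hot]), adj$hotCold)
    }
    # m = 1: numerator is 0 by construction
    v <- array(rnorm(27), c(3, 3, 3)); v[2, 2, 2] <- 100
    ca <- clusterAnalysis(volumeGrid(v), labelMask(array(1L, c(3, 3, 3))), 1L)
    expect_equal(ca$m, 1L)
    expect_equal(ca$clusterIndex, 0)
})

test_that("index 0 whenever no two hot voxels are face-adjacent", {
    dims <- c(6L, 6L, 6L)
    v <- array(0, dims)
    # hot voxels on a sparse diagonal-ish pattern, pairwise non-adjacent
    pts <- rbind(c(1, 1, 1), c(3, 3, 3), c(5, 5, 5), c(1, 4, 2),
                 c(4, 1, 5), c(6, 6, 1), c(2, 6, 4), c(6, 2, 3),
                 c(4, 4, 6), c(1, 6, 6), c(6, 4, 1))
    v[pts] <- 50 + seq_len(nrow(pts))
    ca <- clusterAnalysis(volumeGrid(v), labelMask(array(1L, dims)), 1L,
                          fraction = nrow(pts) / prod(dims))
    expect_equal(ca$meanNhnHot, 0)
    expect_equal(ca$clusterIndex, 0)
})

test_that("cluster index is rank-invariant and discriminates blob from spread", {
    set.seed(BASE_SEED)
    dims <- c(12L, 12L, 12L)
    lm <- labelMask(array(1L, dims))
    v <- array(rgamma(prod(dims), 2), dims)
    i1 <- clusterAnalysis(volumeGrid(v), lm, 1L)$clusterIndex
    i2 <- clusterAnalysis(volumeGrid(exp(v)), lm, 1L)$clusterIndex
    expect_equal(i1, i2, tolerance = 1e-12)

    # fixed hot count: one compact blob beats any scattered configuration
    ctr <- arrayInd(seq_len(prod(dims)), dims)
    d2 <- rowSums((ctr - 6.5)^2)
    blobVals <- array(-d2, dims)          # hottest voxels form a ball
    iBlob <- clusterAnalysis(volumeGrid(blobVals), lm, 1L)$clusterIndex
    for (s in 1:5) {
        set.seed(BASE_SEED + s)
        iRand <- clusterAnalysis(volumeGrid(array(rnorm(prod(dims)), dims)),
                                 lm, 1L)$clusterIndex
        expect_gt(iBlob, iRand)
    }
    expect_gt(iBlob, 1)
})

test_that("permutation null is seeded, reproducible and calibrated", {
    set.seed(BASE_SEED)
    dims <- c(14L, 14L, 14L)
    roi <- array(TRUE, dims)
    vals <- rnorm(prod(dims))
    a <- permutationNull(vals, roi, nPermutations = 60L, seed = BASE_SEED)
    b <- permutationNull(vals, roi, nPermutations = 60L, seed = BASE_SEED)
    expect_identical(a, b)                 # same seed, identical null
    expect_error(permutationNull(vals, roi, nPermutations = 0L), ">= 1")

    # a blob occupying the hot set attains the minimum possible p
    ph <- blobPhantom(seed = BASE_SEED)
    roiVox <- extractRoiVoxels(ph$volume, ph$mask, 1L)
    pn <- permutationNull(roiVox$values, maskArray(ph$mask) == 1L,
                          nPermutations = 99L, seed = BASE_SEED)
    expect_equal(pn$p, 1 / 100)
    expect_gt(pn$observed, 1)
    expect_lt(pn$nullMean, 0.1)
})

test_that("unclustered phantoms give uniform-ish permutation p-values", {
    ps <- vapply(1:10, function(s) {
        mask <- labelMask(array(1L, c(12L, 12L, 12L)))
        vol <- sampleBackground(mask, shape = 4, scale = 1,
                                seed = BASE_SEED + s)
        roiVox <- extractRoiVoxels(vol, mask, 1L)
        permutationNull(roiVox$values, maskArray(mask) == 1L,
                        nPermutations = 49L, seed = BASE_SEED + 100L + s)$p
    }, numeric(1))
    # under the null, p is not systematically small
    expect_gt(mean(ps), 0.2)
    expect_lt(mean(ps < 0.05), 0.3)
})

test_that("hot-voxel masks export as NIfTI", {
    ph <- blobPhantom(seed = BASE_SEED + 5L)
    ca <- clusterAnalysis(ph$volume, ph$mask, 1L)
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeHotMask(ca$hotIndex, ph$mask, f)
    back <- readLabelMask(f)
    expect_identical(which(maskArray(back) == 1L), sort(ca$hotIndex))
})
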