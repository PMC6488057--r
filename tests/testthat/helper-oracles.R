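# Shared fixtures and independent oracles. Base seed for all seeded tests: 42.

BASE_SEED <- 42L

# Brute-force all-pairs NHN oracle: for every ROI voxel, count hot ROI
# voxels at L1 distance exactly 1 by scanning all hot positions.
# Independent of the shift-based implementation.
oracleNHN <- function(hot, roi) {
    d <- dim(roi)
    roiIdx <- which(roi)
    hotIdx <- which(hot & roi)
    out <- array(0L, d)
    if (!length(hotIdx)) return(out)
    P <- arrayInd(roiIdx, d)
    H <- arrayInd(hotIdx, d)
    nhn <- integer(length(roiIdx))
    for (k in seq_along(roiIdx)) {
        dd <- abs(H - matrix(P[k, ], nrow(H), 3, byrow = TRUE))
        nhn[k] <- sum(rowSums(dd) == 1L)
    }
    out[roiIdx] <- nhn
    out
}

# All-pairs face-adjacency counts among/against hot voxels.
oracleAdjacency <- function(hot, roi) {
    d <- dim(roi)
    H <- arrayInd(which(hot & roi), d)
    C <- arrayInd(which(roi & !hot), d)
    hh <- 0L
    if (nrow(H) > 1L)
        for (i in seq_len(nrow(H) - 1L)) {
            dd <- abs(H[(i + 1L):nrow(H), , drop = FALSE] -
                      matrix(H[i, ], nrow(H) - i, 3, byrow = TRUE))
            hh <- hh + sum(rowSums(dd) == 1L)
        }
    hc <- 0L
    if (nrow(H) && nrow(C))
        for (i in seq_len(nrow(H))) {
            dd <- abs(C - matrix(H[i, ], nrow(C), 3, byrow = TRUE))
            hc <- hc + sum(rowSums(dd) == 1L)
        }
    list(hotHot = hh, hotCold = hc)
}

# Exact two-sided signed-rank p by explicit enumeration of every sign
# pattern (2^n rows), midranks for tied |d|.
oracleSignedRank <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    if (!n) return(1)
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.numeric(signs %*% r)
    pLe <- mean(Ws <= w + 1e-9)
    pGe <- mean(Ws >= w - 1e-9)
    min(1, 2 * min(pLe, pGe))
}

# Compact single-muscle paired-limb spec for recovery experiments.
smallPairSpec <- function(targetSI, seed, nClusters = 1L,
                          gammaShape = 4, fwhmMm = 3) {
    phantomSpec(
        muscles = data.frame(
            name = "test_muscle", segment = "lower_leg", label = 1L,
            cx = 17.6, cy = 22.4, cz = 36, ax = 12, ay = 12, az = 18,
            meanSUV = 1.2, gammaShape = gammaShape, targetSI = targetSI,
            nClusters = nClusters, clusterRadiusMm = 5,
            clusterAmplitude = 3, stringsAsFactors = FALSE),
        gridDim = c(44L, 28L, 36L), fwhmMm = fwhmMm, seed = seed)
}

# Measured SI of a paired study's muscle from smoothed SUV volumes.
measuredSI <- function(study, label = 1L) {
    suvD <- voxelwiseSUV(study$dominant$volume, study$meta)
    suvN <- voxelwiseSUV(study$nonDominant$volume, study$meta)
    d <- extractRoiVoxels(suvD, study$dominant$mask, label)
    n <- extractRoiVoxels(suvN, study$nonDominant$mask, label)
    symmetryIndex(mean(d$values), mean(n$values))
}

# Spherical-ROI phantom with one injected compact blob, smoothed.
blobPhantom <- function(seed, amplitude = 10, radiusMm = 8) {
    mask <- ellipsoidMask(c(32L, 32L, 26L), center = c(25.6, 25.6, 26),
                          semiAxes = c(15, 15, 15))
    bg <- sampleBackground(mask, shape = 16, scale = 1, seed = seed)
    inj <- injectHotClusters(bg, mask, 1L, nClusters = 1L,
                             radiusMm = radiusMm, amplitude = amplitude,
                             seed = seed + 1L)
    list(volume = smoothFWHM(inj$volume, 3), mask = mask,
         blob = inj$blobs[[1]])
}
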