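## Site assembly, residence kinetics, selectivity.

test_that("hysteresis state machine reproduces a hand-traced event list", {
    ## RMSD 3,5,8,9 stay bound (tolerance band), 12 unbinds; 4 rebinds,
    ## 11 unbinds: bound frames {1..4} and {6}
    ev <- residenceEvents(c(3, 5, 8, 9, 12, 4, 11), dt = 1)
    expect_equal(nrow(ev), 2L)
    expect_equal(ev$start_frame, c(1L, 6L))
    expect_equal(ev$end_frame, c(4L, 6L))
    expect_equal(ev$duration_ns, c(4, 1))
})

test_that("always-unbound and always-bound series are degenerate cases", {
    expect_equal(nrow(residenceEvents(rep(12, 50), dt = 1)), 0L)
    ev <- residenceEvents(rep(2, 50), dt = 2)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$duration_ns, 100)
    expect_error(residenceEvents(c(3, NA, 5)), "non-finite")
    expect_error(residenceEvents(1:3, boundCutoff = 8, unboundCutoff = 6),
                 "unboundCutoff")
})

test_that("the tolerance band keeps partial unbinding inside one event", {
    ## excursions into (6, 10.8] do not split events
    rmsd <- c(3, 7, 10, 7, 3, 10.7, 4)
    ev <- residenceEvents(rmsd, dt = 1)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$duration_ns, 7)
    ## with a tight upper cutoff the same series fragments
    evTight <- residenceEvents(rmsd, boundCutoff = 6, unboundCutoff = 6.0001,
                               dt = 1)
    expect_gt(nrow(evTight), 1L)
})

test_that("widening the upper cutoff never shortens any event", {
    set.seed(15)
    for (i in 1:200) {
        rmsd <- runif(40, 0, 15)
        evN <- residenceEvents(rmsd, 6, 6.0001, dt = 1)
        evW <- residenceEvents(rmsd, 6, 10.8, dt = 1)
        for (j in seq_len(nrow(evN))) {
            k <- which(evW$start_frame <= evN$start_frame[j] &
                       evW$end_frame >= evN$end_frame[j])
            expect_length(k, 1L)
            expect_gte(evW$duration_ns[k], evN$duration_ns[j])
        }
    }
})

test_that("events on concatenated halves equal events on the full series", {
    set.seed(16)
    rmsd <- runif(60, 0, 15)
    full <- residenceEvents(rmsd, dt = 1)
    cut <- 30L
    ## choose a cut not straddled by an event
    straddle <- any(full$start_frame <= cut & full$end_frame > cut)
    if (!straddle) {
        a <- residenceEvents(rmsd[1:cut], dt = 1)
        b <- residenceEvents(rmsd[(cut + 1):60], dt = 1)
        b$start_frame <- b$start_frame + cut
        b$end_frame <- b$end_frame + cut
        got <- rbind(a[names(full)[1:2]], b[names(full)[1:2]])
        expect_equal(got$start_frame, full$start_frame)
        expect_equal(got$end_frame, full$end_frame)
    } else {
        succeed()
    }
})

test_that("event durations recover a planted exponential dwell", {
    spec <- syntheticSpec(nFrames = 6000L, dt = 10, seed = 21L,
                          plantedSites = list(
                              list(name = "P1", helices = c(1L, 2L),
                                   meanDwell = 300, captureRadius = 8,
                                   bindProb = 0.7)),
                          nMonomers = 2L)
    sys <- suppressMessages(generateSystem(spec))
    dur <- sys$groundTruth$events$duration_ns
    dur <- dur[sys$groundTruth$events$end_frame < spec$nFrames]
    expect_gte(length(dur), 100L)
    expect_equal(mean(dur), 300, tolerance = 0.2)
    ## survival consistent with the planted rate (discretized to dt)
    ks <- suppressWarnings(stats::ks.test(dur, "pexp", 1 / 300))
    expect_gt(ks$p.value, 0.01)
})

test_that("outliers match hotspots and reproducibility filters systems", {
    topo <- makeToyTopology(nRes = 3L, nLip = 1L)
    ref <- rbind(c(5, 5, 5), c(20, 20, 20), c(40, 40, 5), c(0, 0, 0))
    mkHot <- function(center, peak) {
        new("Hotspot", id = 1L, voxels = matrix(1L, 1, 3),
            centers = matrix(center, 1, 3), peak = peak,
            centroid = center, volume = 1)
    }
    hps <- list(SYS1 = list(mkHot(c(5, 5, 6), 100), mkHot(c(40, 40, 6), 50)),
                SYS2 = list(mkHot(c(5, 6, 5), 90), mkHot(c(40, 41, 6), 60)),
                SYS3 = list(mkHot(c(6, 5, 5), 95)))
    got <- matchOutliersToHotspots(outlierIds = c(1L, 3L), hps, topo, ref,
                                   matchRadius = 6, groupRadius = 6,
                                   residueMask = 1:3)
    ## the blob near residue 3 is absent from SYS3: not reproducible
    expect_length(got$sites, 1L)
    expect_equal(got$sites[[1]]@outlierIds, 1L)
    expect_equal(got$sites[[1]]@residueIds, 1L)
    expect_true(got$sites[[1]]@ranked)
    expect_equal(nrow(got$nonReproducible), 1L)
    ## an outlier bead inside a hotspot voxel matches at radius 0
    got0 <- matchOutliersToHotspots(1L, lapply(hps, function(h) h[1]),
                                    topo, rbind(c(5, 5, 6), ref[-1, ]),
                                    matchRadius = 0, residueMask = 1:3)
    expect_length(got0$sites, 1L)
    ## hotspot groups with no outlier become density-only candidates
    gotC <- matchOutliersToHotspots(integer(), lapply(hps, function(h) h[1]),
                                    topo, ref, residueMask = 1:3)
    expect_length(gotC$sites, 1L)
    expect_false(gotC$sites[[1]]@ranked)
    expect_match(gotC$sites[[1]]@name, "^C")
})

test_that("topology classification separates linear stretches from 3-D pockets", {
    mkSite <- function(ids) new("InteractionSite", name = "x",
                                residueIds = as.integer(ids),
                                outlierIds = integer(),
                                hotspotIds = character(),
                                topologyClass = NA_character_,
                                nBindingModes = NA_integer_,
                                peakDensity = 1, centroid = c(0, 0, 0),
                                voxelCenters = matrix(0, 1, 3),
                                ranked = TRUE)
    seg <- c(`265` = "TM4", `267` = "TM4", `268` = "TM4", `272` = "TM4",
             `10` = "TM1", `100` = "TM3", `200` = "TM7")
    lin <- classifyTopology(mkSite(c(265, 267, 268, 272)), seg)
    expect_equal(lin@topologyClass, "linear")
    non <- classifyTopology(mkSite(c(10, 100, 200)), seg)
    expect_equal(non@topologyClass, "non-linear")
    single <- classifyTopology(mkSite(265), seg)
    expect_equal(single@topologyClass, "linear")
    ## same segment but a long span is not linear
    seg2 <- c(`1` = "TM1", `50` = "TM1")
    expect_equal(classifyTopology(mkSite(c(1, 50)), seg2)@topologyClass,
                 "non-linear")
    expect_error(classifyTopology(mkSite(999), seg), "unannotated")
})

test_that("reference bound poses maximize site density with earliest-frame ties", {
    counts <- array(0L, dim = c(10, 10, 10))
    counts[5, 5, 5] <- 100L
    counts[8, 8, 8] <- 60L
    g <- new("DensityGrid", origin = c(0, 0, 0), edge = 1, counts = counts,
             nFrames = 1L, refDensity = 0.1, nOutside = 0L, species = "CHOL")
    site <- new("InteractionSite", name = "S", residueIds = 1L,
                outlierIds = integer(), hotspotIds = character(),
                topologyClass = NA_character_, nBindingModes = NA_integer_,
                peakDensity = 100, centroid = c(4.5, 4.5, 4.5),
                voxelCenters = matrix(c(4.5, 4.5, 4.5), 1, 3), ranked = TRUE)
    lc <- array(0, dim = c(4, 1, 3))
    lc[1, 1, ] <- c(1, 1, 1)       # outside the site
    lc[2, 1, ] <- c(4.2, 4.2, 4.2) # in the peak voxel
    lc[3, 1, ] <- c(4.6, 4.6, 4.6) # same voxel (tie)
    lc[4, 1, ] <- c(7.5, 7.5, 7.5) # other blob, not in the site
    pose <- referenceBoundPose(lc, site, g)
    expect_equal(pose$frame, 2L)   # earliest of the tied frames
    rmsd <- poseRMSD(lc, pose$coords)
    expect_equal(rmsd[2], 0)
    ## a lipid that never enters the site has no pose
    far <- array(rep(c(1, 1, 1), each = 3), dim = c(3, 1, 3))
    expect_null(referenceBoundPose(far, site, g))
})

test_that("site summaries count events and threshold crossings", {
    mkEv <- function(durs, mols) data.frame(
        start_frame = 1, end_frame = 2, start_ns = 0, end_ns = durs,
        duration_ns = durs, molecule_id = mols)
    s <- summarizeSite(list(a = mkEv(c(500, 1500, 3000), c(1, 1, 2)),
                            b = mkEv(2300, 7)))
    expect_equal(s$n_events_total, 4L)
    expect_equal(s$n_events_gt_threshold, 3L)
    expect_equal(s$max_residence_us, 3)
    expect_equal(s$mean_visiting_lipids, mean(c(2, 1)))
    one <- summarizeSite(list(a = mkEv(2300, 1)))
    expect_equal(one$n_events_total, 1L)
    expect_equal(one$n_events_gt_threshold, 1L)
    empty <- summarizeSite(list())
    expect_equal(empty$n_events_total, 0L)
})

test_that("binding-mode clustering counts orientations and flags noise", {
    one <- matrix(rep(c(1, 2, 3, 4, 5, 6), 40), nrow = 40, byrow = TRUE)
    m1 <- countBindingModes(one, clusterRmsd = 4)
    expect_equal(m1$n_modes, 1L)
    expect_false(m1$low_confidence)
    ## two orientations of a two-bead pose, 90 degrees apart
    a <- c(0, 0, 0, 10, 0, 0)
    b <- c(0, 0, 0, 0, 10, 0)
    two <- rbind(matrix(rep(a, 30), ncol = 6, byrow = TRUE),
                 matrix(rep(b, 30), ncol = 6, byrow = TRUE)) +
        matrix(rnorm(360, sd = 0.2), ncol = 6)
    m2 <- countBindingModes(two, clusterRmsd = 4)
    expect_equal(m2$n_modes, 2L)
    ## structureless poses: qualifying modes cover little of the data
    set.seed(17)
    noise <- matrix(runif(600, 0, 100), ncol = 6)
    m3 <- countBindingModes(noise, clusterRmsd = 2, minFraction = 0.05)
    expect_true(m3$low_confidence)
})

test_that("minimum-distance series is symmetric and matches brute force", {
    sys <- randomToySystem(18, nFrames = 6L)
    ga <- residueBeads(sys$topology, 1)
    gb <- lipidBeads(sys$topology, 2)
    d1 <- minDistanceTimeseries(sys$trajectory, ga, gb)
    d2 <- minDistanceTimeseries(sys$trajectory, gb, ga)
    expect_equal(d1, d2)
    expect_equal(minDistanceTimeseries(sys$trajectory, ga, ga),
                 rep(0, 6))
    ## brute force over all pairs and 27 images
    f <- 3L
    fr <- beadCoords(sys$trajectory, f)
    box <- boxLengths(sys$trajectory, f)
    img <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    best <- Inf
    for (i in ga) for (j in gb) for (k in seq_len(nrow(img)))
        best <- min(best, sqrt(sum((fr[i, ] - fr[j, ] - img[k, ] * box)^2)))
    expect_equal(d1[f], best, tolerance = 1e-12)
})

test_that("selectivity labels cholesterol-exclusive sites non-annular", {
    mkGrid <- function(val) {
        counts <- array(0L, dim = c(10, 10, 10))
        counts[5, 5, 5] <- as.integer(val)
        new("DensityGrid", origin = c(0, 0, 0), edge = 1, counts = counts,
            nFrames = 10L, refDensity = 0.01, nOutside = 0L, species = "x")
    }
    site <- new("InteractionSite", name = "S", residueIds = c(1L, 2L),
                outlierIds = 1L, hotspotIds = "SYS1:1",
                topologyClass = NA_character_, nBindingModes = NA_integer_,
                peakDensity = 100, centroid = c(4.5, 4.5, 4.5),
                voxelCenters = matrix(c(4.5, 4.5, 4.5), 1, 3), ranked = TRUE)
    prof <- data.frame(residue_id = c(1L, 2L, 1L, 2L),
                       species = c("CHOL", "CHOL", "PC", "PC"),
                       mean_tmax_ns = c(2000, 1500, 20, 10),
                       contacted = TRUE)
    sel <- siteSelectivity(site, prof,
                           list(CHOL = mkGrid(500), PC = mkGrid(0)))
    expect_true(sel$non_annular)
    expect_equal(sel$perSpecies$mean_tmax_ns[sel$perSpecies$species == "CHOL"],
                 1750)
    selEq <- siteSelectivity(site, prof,
                             list(CHOL = mkGrid(500), PC = mkGrid(500)))
    expect_false(selEq$non_annular)
})
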