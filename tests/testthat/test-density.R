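## Spatial density probability function and hotspot extraction.

test_that("a stationary bead yields the closed-form density V/n in its voxel", {
    topo <- makeToyTopology(nRes = 1L, nLip = 4L)
    nFramesV <- 25L
    box <- c(20, 30, 40)
    co <- array(0, dim = c(nFramesV, 5, 3))
    co[, 1, ] <- matrix(rep(c(10, 10, 10), each = nFramesV), ncol = 3)
    co[, 2, ] <- matrix(rep(c(5.5, 5.5, 5.5), each = nFramesV), ncol = 3)
    ## other species beads parked outside the grid
    for (b in 3:5)
        co[, b, ] <- matrix(rep(c(-100, -100, -100), each = nFramesV), ncol = 3)
    traj <- makeToyTrajectory(co, box = box)
    g <- computeSDF(traj, topo, species = "CHOL", fit = FALSE,
                    grid = list(origin = c(0, 0, 0), dims = c(12, 12, 12)))
    vals <- densityValues(g)
    V <- prod(box); n <- 4
    expect_equal(vals[6, 6, 6], V / n)
    expect_equal(sum(vals > 0), 1L)
    expect_equal(sum(voxelCounts(g)), nFramesV)
    expect_equal(g@nOutside, 3L * nFramesV)
})

test_that("uniformly scattered beads give a voxel-mean density near one", {
    topo <- makeToyTopology(nRes = 1L, nLip = 50L)
    set.seed(12)
    nf <- 40L
    box <- c(20, 20, 20)
    co <- array(runif(nf * 51 * 3, 0, 20), dim = c(nf, 51, 3))
    traj <- makeToyTrajectory(co, box = box)
    g <- computeSDF(traj, topo, species = "CHOL", fit = FALSE,
                    grid = list(origin = c(0, 0, 0), dims = c(20, 20, 20)))
    ## 50 of 51 beads are CHOL; rho counts CHOL beads only, and the grid
    ## covers the whole box, so the voxel mean of g estimates 1
    expect_equal(mean(densityValues(g)), 1, tolerance = 0.05)
})

test_that("grid merging equals density on the concatenated trajectory", {
    sys <- randomToySystem(13, nFrames = 16L, nLip = 8L)
    traj <- sys$trajectory
    geom <- list(origin = c(0, 0, 0), dims = c(30, 30, 30))
    full <- computeSDF(traj, sys$topology, fit = FALSE, grid = geom)
    half1 <- traj; half1@coords <- traj@coords[1:8, , , drop = FALSE]
    half1@box <- traj@box[1:8, , drop = FALSE]; half1@times <- traj@times[1:8]
    half2 <- traj; half2@coords <- traj@coords[9:16, , , drop = FALSE]
    half2@box <- traj@box[9:16, , drop = FALSE]; half2@times <- traj@times[9:16]
    g1 <- computeSDF(half1, sys$topology, fit = FALSE, grid = geom)
    g2 <- computeSDF(half2, sys$topology, fit = FALSE, grid = geom)
    merged <- mergeGrids(list(g1, g2))
    expect_identical(voxelCounts(merged), voxelCounts(full))
    expect_equal(densityValues(merged), densityValues(full))
    ## merging an empty grid is the identity
    empty <- g1; empty@counts[] <- 0L; empty@nFrames <- 0L; empty@nOutside <- 0L
    expect_identical(voxelCounts(mergeGrids(list(full, empty))),
                     voxelCounts(full))
    ## merging k copies leaves the normalized density unchanged
    g3 <- mergeGrids(list(full, full, full))
    expect_equal(densityValues(g3), densityValues(full))
    bad <- g1; bad@origin <- bad@origin + 1
    expect_error(mergeGrids(list(g1, bad)), "geometry mismatch")
})

test_that("density is invariant to rigid-body motion when fitting is enabled", {
    set.seed(14)
    topo <- makeToyTopology(nRes = 4L, beadsPerRes = 2L, nLip = 6L)
    nb <- nBeads(topo)
    base <- matrix(runif(nb * 3, 10, 30), ncol = 3)
    nf <- 10L
    still <- array(rep(base, each = nf), dim = c(nf, nb, 3))
    moved <- array(0, dim = c(nf, nb, 3))
    for (f in 1:nf) {
        th <- runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
        moved[f, , ] <- sweep(base %*% t(R), 2, runif(3, -5, 5), "+")
    }
    geom <- list(origin = c(0, 0, 0), dims = c(40, 40, 40))
    sel <- residueBeads(topo)
    gStill <- computeSDF(makeToyTrajectory(still), topo, fit = FALSE,
                         grid = geom)
    gMoved <- computeSDF(makeToyTrajectory(moved), topo, fit = TRUE,
                         fitSelection = sel, reference = base, grid = geom)
    expect_identical(voxelCounts(gMoved), voxelCounts(gStill))
})

test_that("hotspot extraction finds separated blobs and honors the contour", {
    counts <- array(0L, dim = c(30, 30, 30))
    blob <- function(center, amp) {
        for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
            v <- center + c(dx, dy, dz)
            counts[v[1], v[2], v[3]] <<-
                counts[v[1], v[2], v[3]] +
                as.integer(round(amp * exp(-sum(c(dx, dy, dz)^2) / 2)))
        }
    }
    blob(c(8, 8, 8), 100)
    blob(c(22, 22, 22), 80)
    g <- new("DensityGrid", origin = c(0, 0, 0), edge = 1, counts = counts,
             nFrames = 10L, refDensity = 0.01, nOutside = 0L,
             species = "CHOL")
    hs <- extractHotspots(g, contour = 20, minVoxels = 3)
    expect_length(hs, 2L)
    expect_equal(hs[[1]]@peak, 100)
    expect_lt(sqrt(sum((hs[[1]]@centroid - c(7.5, 7.5, 7.5))^2)), 1)
    expect_lt(sqrt(sum((hs[[2]]@centroid - c(21.5, 21.5, 21.5))^2)), 1)
    ## below-contour grids give nothing
    expect_length(extractHotspots(g, contour = 1000), 0L)
    ## raising the contour never increases count or total volume
    vols <- function(h) sum(vapply(h, function(x) x@volume, 0))
    h1 <- extractHotspots(g, contour = 10, minVoxels = 1)
    h2 <- extractHotspots(g, contour = 40, minVoxels = 1)
    expect_lte(length(h2), length(h1))
    expect_lte(vols(h2), vols(h1))
    ## 6-connectivity splits no more than 26-connectivity merges
    h26 <- extractHotspots(g, contour = 20, minVoxels = 1, connectivity = 26)
    h6 <- extractHotspots(g, contour = 20, minVoxels = 1, connectivity = 6)
    expect_gte(length(h6), length(h26))
})

test_that("OpenDX output carries the grid shape and values", {
    counts <- array(seq_len(8), dim = c(2, 2, 2))
    g <- new("DensityGrid", origin = c(1, 2, 3), edge = 1, counts = counts,
             nFrames = 1L, refDensity = 1, nOutside = 0L, species = "CHOL")
    f <- withr::local_tempfile(fileext = ".dx")
    writeOpenDX(g, f)
    lines <- readLines(f)
    expect_match(lines[1], "counts 2 2 2")
    dataStart <- grep("data follows", lines)
    vals <- as.numeric(unlist(strsplit(trimws(
        lines[(dataStart + 1):(dataStart + ceiling(8 / 3))]), "\\s+")))
    ## dx order: last index fastest
    expect_equal(vals, as.numeric(counts[cbind(rep(1:2, each = 4),
                                               rep(rep(1:2, each = 2), 2),
                                               rep(1:2, 4))]))
})
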