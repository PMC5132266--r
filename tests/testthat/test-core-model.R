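## Topology/trajectory I/O, periodic distances, superposition.

groLine <- function(resid, resname, atname, atnr, xyzA) {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid, resname, atname, atnr,
            xyzA[1] / 10, xyzA[2] / 10, xyzA[3] / 10)
}

writeTinyGro <- function(path, time = NULL) {
    ## 1 protein residue (3 beads) + 1 CHOL (8 beads)
    lines <- c(if (is.null(time)) "tiny system"
               else sprintf("tiny system t= %.3f", time),
               sprintf("%5d", 11L))
    at <- 0L
    for (b in 1:3) {
        at <- at + 1L
        lines <- c(lines, groLine(1L, "ALA", "BB", at, c(10 + b, 10, 10)))
    }
    for (b in 1:8) {
        at <- at + 1L
        lines <- c(lines, groLine(2L, "CHOL", "C", at, c(20, 10 + b, 10)))
    }
    lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", 5, 5, 5))
    writeLines(lines, path)
    path
}

test_that("GRO topology reading assigns residues, lipids and species", {
    f <- withr::local_tempfile(fileext = ".gro")
    writeTinyGro(f)
    topo <- readTopology(f)
    expect_equal(nrow(residues(topo)), 1L)
    expect_equal(nrow(lipids(topo)), 1L)
    expect_equal(nBeads(topo), 11L)
    expect_equal(lipids(topo)$species, "CHOL")
    expect_equal(length(residueBeads(topo)), 3L)
    expect_equal(length(lipidBeads(topo)), 8L)
})

test_that("species map classifies POPE as PE and unknown names as OTHER", {
    f <- withr::local_tempfile(fileext = ".gro")
    lines <- c("two lipids", sprintf("%5d", 2L),
               groLine(1L, "POPE", "P", 1L, c(1, 1, 1)),
               groLine(2L, "XXXX", "X", 2L, c(2, 2, 2)),
               sprintf("%10.5f%10.5f%10.5f", 5, 5, 5))
    writeLines(lines, f)
    expect_warning(topo <- readTopology(f), "OTHER")
    expect_equal(lipids(topo)$species, c("PE", "OTHER"))
})

test_that("degenerate and malformed topology files raise format errors", {
    f <- withr::local_tempfile(fileext = ".gro")
    writeLines(character(), f)
    expect_error(readTopology(f), "format error")
    writeLines(c("bad", "notanumber", "x"), f)
    expect_error(readTopology(f), "format error")
    expect_error(readTopology(file.path(tempdir(), "nope.gro")),
                 "does not exist")
})

test_that("equilibration discard keeps frames at or after the cutoff time", {
    spec <- syntheticSpec(nFrames = 10L, dt = 100, box = c(60, 60, 60),
                          plantedSites = NULL, nHelices = 2L,
                          residuesPerHelix = 2L, nMonomers = 1L,
                          areaPerLipid = 400, seed = 2L)
    sys <- generateSystem(spec)
    d <- withr::local_tempdir()
    paths <- writeFixture(sys, d)
    topo <- readTopology(paths[["topology"]])
    tr <- readTrajectory(paths[["trajectory"]], topo, discardInitial = 500)
    expect_equal(nFrames(tr), 5L)  # times 500..900 of 0..900
    tr0 <- readTrajectory(paths[["trajectory"]], topo, discardInitial = 0)
    expect_equal(nFrames(tr0), 10L)
    expect_equal(frameInterval(tr0), 100)
    expect_error(readTrajectory(paths[["trajectory"]], topo,
                                discardInitial = 1e6),
                 "empty trajectory")
})

test_that("trajectory reading validates bead counts against the topology", {
    spec <- syntheticSpec(nFrames = 3L, box = c(60, 60, 60),
                          plantedSites = NULL, nHelices = 2L,
                          residuesPerHelix = 2L, nMonomers = 1L,
                          areaPerLipid = 400, seed = 3L)
    sys <- generateSystem(spec)
    d <- withr::local_tempdir()
    paths <- writeFixture(sys, d)
    tiny <- withr::local_tempfile(fileext = ".gro")
    writeTinyGro(tiny)
    wrongTopo <- readTopology(tiny)
    expect_error(readTrajectory(paths[["trajectory"]], wrongTopo),
                 "topology mismatch")
})

test_that("topology and coordinates round-trip through GRO exactly", {
    spec <- syntheticSpec(nFrames = 4L, box = c(60, 60, 60),
                          plantedSites = NULL, nHelices = 2L,
                          residuesPerHelix = 3L, nMonomers = 2L,
                          areaPerLipid = 300, seed = 4L)
    sys <- generateSystem(spec)
    d <- withr::local_tempdir()
    paths <- writeFixture(sys, d)
    topo <- readTopology(paths[["topology"]],
                         monomerFile = paths[["monomers"]],
                         membraneFacingFile = paths[["facing"]],
                         speciesMap = readSpeciesMap(paths[["species"]]))
    expect_equal(residues(topo)$residue_id, residues(sys$topology)$residue_id)
    expect_equal(residues(topo)$monomer, residues(sys$topology)$monomer)
    expect_equal(lipids(topo)$species, lipids(sys$topology)$species)
    expect_equal(topo@beads$owner, sys$topology@beads$owner)
    expect_equal(topo@beads$owner_id, sys$topology@beads$owner_id)
    tr <- readTrajectory(paths[["trajectory"]], topo)
    ## GRO stores 0.001 nm = 0.01 Angstrom precision
    expect_lt(max(abs(tr@coords - sys$trajectory@coords)), 0.0051)
    expect_equal(tr@box, sys$trajectory@box)
})

test_that("triclinic boxes are rejected", {
    f <- withr::local_tempfile(fileext = ".gro")
    lines <- c("tri", sprintf("%5d", 1L),
               groLine(1L, "CHOL", "C", 1L, c(1, 1, 1)),
               "   5.00000   5.00000   5.00000   0.00000   0.00000   1.00000   0.00000   0.00000   0.00000")
    writeLines(lines, f)
    expect_error(readTopology(f), "triclinic")
})

test_that("minimum-image distances match an explicit 27-image enumeration", {
    expect_equal(minImageDistance(c(1, 2, 3), c(1, 2, 3), c(10, 10, 10)), 0)
    expect_equal(minImageDistance(c(1, 0, 0), c(99, 0, 0), c(100, 100, 100)), 2)
    oracle <- function(a, b, box) {
        img <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
        min(apply(img, 1, function(s) sqrt(sum((a - b - s * box)^2))))
    }
    set.seed(1)
    for (i in 1:50) {
        box <- runif(3, 5, 30)
        a <- runif(3, 0, 1) * box  # in-box: +/- 1 image enumeration is exact
        b <- runif(3, 0, 1) * box
        expect_equal(minImageDistance(a, b, box), oracle(a, b, box),
                     tolerance = 1e-12)
    }
})

test_that("minimum-image distance is symmetric and respects the triangle inequality", {
    set.seed(2)
    box <- c(20, 25, 30)
    for (i in 1:30) {
        a <- runif(3, 0, box); b <- runif(3, 0, box); c <- runif(3, 0, box)
        dab <- minImageDistance(a, b, box)
        expect_equal(dab, minImageDistance(b, a, box))
        expect_lte(dab,
                   minImageDistance(a, c, box) +
                   minImageDistance(c, b, box) + 1e-12)
        expect_lte(dab, sqrt(sum((box / 2)^2)) + 1e-12)
    }
})

test_that("Kabsch superposition recovers exact transforms and beats no fit", {
    set.seed(3)
    ref <- matrix(rnorm(60, sd = 5), ncol = 3)
    idem <- fitFrame(ref, ref, 1:20)
    expect_equal(idem$superposition@rmsdAfter, 0, tolerance = 1e-10)
    expect_equal(idem$superposition@rotation, diag(3), tolerance = 1e-8)
    ## 90 degree rotation about z plus translation
    R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
    moved <- sweep(ref %*% t(R), 2, c(5, -3, 2), "+")
    fit <- fitFrame(moved, ref, 1:20)
    expect_equal(fit$superposition@rmsdAfter, 0, tolerance = 1e-8)
    expect_equal(fit$coords, ref, tolerance = 1e-8)
    expect_equal(det(fit$superposition@rotation), 1, tolerance = 1e-10)
})

test_that("noisy superposition matches the independent bio3d solver", {
    set.seed(4)
    ref <- matrix(rnorm(45, sd = 4), ncol = 3)
    noisy <- sweep(ref %*% t(matrix(c(cos(.3), sin(.3), 0,
                                      -sin(.3), cos(.3), 0,
                                      0, 0, 1), 3, 3)), 2, c(1, 2, 3), "+") +
        matrix(rnorm(45, sd = 0.3), ncol = 3)
    fit <- fitFrame(noisy, ref, 1:15)
    expect_lte(fit$superposition@rmsdAfter, fit$superposition@rmsdBefore)
    oracle <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                                              mobile = as.numeric(t(noisy))))
    oracleRmsd <- sqrt(mean(rowSums(
        (matrix(oracle, ncol = 3, byrow = TRUE) - ref)^2)))
    expect_equal(fit$superposition@rmsdAfter, oracleRmsd, tolerance = 1e-6)
    ## idempotence: refitting a fitted frame moves nothing
    again <- fitFrame(fit$coords, ref, 1:15)
    expect_lt(max(abs(again$coords - fit$coords)), 1e-6)
})

test_that("degenerate fit selections are rejected", {
    ref <- matrix(rnorm(30), ncol = 3)
    expect_error(fitFrame(ref, ref, 1:2), "at least 3")
    line <- cbind(1:10, 2 * (1:10), 3 * (1:10))  # collinear
    expect_error(fitFrame(line, line, 1:10), "collinear")
})
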