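#' Spatial density probability function of lipid beads
#'
#' Accumulates per-voxel hit counts of the chosen lipid species around
#' the protein after superposing every frame onto a reference structure
#' (Kabsch fit over `fitSelection`), and stores the normalization
#' g = N / (rho * dV * n_frames) whose bulk average is one.  The
#' reference density rho is the number of species beads divided by the
#' reference-frame box volume.
#'
#' @param traj A [Trajectory-class].
#' @param topology A [BeadTopology-class].
#' @param species Lipid species to bin (single species, default
#'   `"CHOL"`).
#' @param fitSelection Bead indices to superpose on (default: beads of
#'   all membrane-facing residues).
#' @param voxel Voxel edge in Angstrom (default 1, i.e. 1 A^3 volume
#'   elements suited to coarse-grained bead sizes).
#' @param reference Beads x 3 reference coordinates (default frame 1).
#' @param grid Optional list with `origin` (length 3) and `dims`
#'   (length 3) fixing the lattice geometry, e.g. taken from another
#'   grid so results can be merged; default: reference-frame protein
#'   bounding box plus `margin`.
#' @param margin Grid margin around the protein bounding box (Angstrom).
#' @param fit Superpose frames before binning (default TRUE).
#' @param refSelection Bead indices in `reference` corresponding to
#'   `fitSelection` (default the same), for fitting one monomer onto
#'   another.
#' @return A [DensityGrid-class].  Beads falling outside the grid are
#'   not binned but tallied in the `nOutside` slot.
#' @export
computeSDF <- function(traj, topology, species = "CHOL",
                       fitSelection = NULL, voxel = 1,
                       reference = NULL, grid = NULL, margin = 15,
                       fit = TRUE, refSelection = fitSelection) {
    if (nFrames(traj) < 1L)
        stop("need at least one frame")
    if (is.null(reference))
        reference <- beadCoords(traj, 1L)
    if (is.null(fitSelection)) {
        fitSelection <- residueBeads(topology, membraneFacing(topology))
        refSelection <- fitSelection
    }
    if (is.null(refSelection))
        refSelection <- fitSelection
    spBeads <- lipidBeads(topology, species = species)
    if (!length(spBeads))
        stop(sprintf("no beads of species %s", species))
    if (is.null(grid)) {
        pb <- reference[residueBeads(topology), , drop = FALSE]
        origin <- floor(apply(pb, 2, min) - margin)
        upper <- ceiling(apply(pb, 2, max) + margin)
        dims <- as.integer(ceiling((upper - origin) / voxel))
    } else {
        origin <- grid$origin
        dims <- as.integer(grid$dims)
    }
    nf <- nFrames(traj)
    ## voxel linear indices for all bead-frame observations, one
    ## tabulate at the end
    linAll <- vector("list", nf)
    nOutside <- 0L
    for (f in seq_len(nf)) {
        fr <- beadCoords(traj, f)
        if (fit)
            fr <- fitFrame(fr, reference, fitSelection, refSelection)$coords
        p <- fr[spBeads, , drop = FALSE]
        ix <- floor(sweep(p, 2, origin) / voxel) + 1
        ok <- ix[, 1] >= 1 & ix[, 1] <= dims[1] &
            ix[, 2] >= 1 & ix[, 2] <= dims[2] &
            ix[, 3] >= 1 & ix[, 3] <= dims[3]
        nOutside <- nOutside + sum(!ok)
        ix <- ix[ok, , drop = FALSE]
        if (nrow(ix))
            linAll[[f]] <- ix[, 1] + dims[1] * (ix[, 2] - 1) +
                dims[1] * dims[2] * (ix[, 3] - 1)
    }
    counts <- array(tabulate(unlist(linAll), nbins = prod(dims)),
                    dim = dims)
    boxRef <- boxLengths(traj, 1L)
    rho <- length(spBeads) / prod(boxRef)
    new("DensityGrid", origin = as.numeric(origin), edge = voxel,
        counts = counts, nFrames = nf, refDensity = rho,
        nOutside = nOutside, species = species)
}

#' Merge density grids with identical geometry
#'
#' Counts and frame numbers are summed; the normalized density is
#' recomputed from the sums, so merging two half-trajectories equals
#' computing one grid on the concatenated trajectory.
#'
#' @param grids A list of [DensityGrid-class] objects sharing origin,
#'   voxel edge, shape, species and reference density.
#' @return A [DensityGrid-class].
#' @export
mergeGrids <- function(grids) {
    stopifnot(length(grids) >= 1L)
    g1 <- grids[[1]]
    for (g in grids[-1]) {
        if (any(abs(g@origin - g1@origin) > 1e-9) ||
            abs(g@edge - g1@edge) > 1e-12 ||
            !identical(dim(g@counts), dim(g1@counts)))
            stop("geometry mismatch: grids must share origin, voxel and shape")
        if (g@species != g1@species)
            stop("species mismatch")
        if (abs(g@refDensity - g1@refDensity) > 1e-6 * g1@refDensity)
            stop("reference density mismatch")
    }
    out <- g1
    for (g in grids[-1]) {
        out@counts <- out@counts + g@counts
        out@nFrames <- out@nFrames + g@nFrames
        out@nOutside <- out@nOutside + g@nOutside
    }
    out
}

## 26-connected neighbor offsets (or 6-connected)
.connOffsets <- function(connectivity) {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
    if (connectivity == 6)
        off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
    off
}

#' Extract high-density hotspots from a density grid
#'
#' Thresholds the raw per-voxel hit counts at `contour` (hits per
#' voxel) and returns the connected components (26-connectivity by
#' default) with at least `minVoxels` member voxels, sorted by
#' decreasing peak count.
#'
#' @param grid A [DensityGrid-class].
#' @param contour Contour level in hits per voxel (> 0); voxels with
#'   counts >= contour are kept.
#' @param minVoxels Minimum component size (default 5, suppressing
#'   single-voxel noise).
#' @param connectivity 26 (default) or 6.
#' @return A list of [Hotspot-class] objects (possibly empty).
#' @export
extractHotspots <- function(grid, contour, minVoxels = 5L,
                            connectivity = c(26, 6)) {
    connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
    connectivity <- as.integer(connectivity)
    if (contour <= 0)
        stop("contour must be positive")
    counts <- grid@counts
    dims <- dim(counts)
    super <- which(counts >= contour)
    if (!length(super))
        return(list())
    lab <- array(0L, dim = dims)
    lab[super] <- -1L  # unvisited super-threshold
    off <- .connOffsets(connectivity)
    comps <- list()
    for (s in super) {
        if (lab[s] != -1L)
            next
        id <- length(comps) + 1L
        queue <- s
        lab[s] <- id
        members <- integer()
        while (length(queue)) {
            v <- queue[[length(queue)]]
            queue <- queue[-length(queue)]
            members <- c(members, v)
            v0 <- v - 1L
            ix <- v0 %% dims[1] + 1L
            iy <- (v0 %/% dims[1]) %% dims[2] + 1L
            iz <- v0 %/% (dims[1] * dims[2]) + 1L
            nb <- cbind(ix + off[, 1], iy + off[, 2], iz + off[, 3])
            ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
                nb[, 2] >= 1 & nb[, 2] <= dims[2] &
                nb[, 3] >= 1 & nb[, 3] <= dims[3]
            nb <- nb[ok, , drop = FALSE]
            lin <- nb[, 1] + dims[1] * (nb[, 2] - 1) +
                dims[1] * dims[2] * (nb[, 3] - 1)
            new <- lin[lab[lin] == -1L]
            lab[new] <- id
            queue <- c(queue, new)
        }
        comps[[id]] <- members
    }
    comps <- comps[vapply(comps, length, 0L) >= minVoxels]
    if (!length(comps))
        return(list())
    hs <- lapply(comps, function(m) {
        m0 <- m - 1L
        vox <- cbind(m0 %% dims[1] + 1L,
                     (m0 %/% dims[1]) %% dims[2] + 1L,
                     m0 %/% (dims[1] * dims[2]) + 1L)
        centers <- sweep((vox - 0.5) * grid@edge, 2, grid@origin, "+")
        w <- as.numeric(counts[m])
        centroid <- colSums(centers * w) / sum(w)
        new("Hotspot", id = NA_integer_, voxels = vox, centers = centers,
            peak = max(w), centroid = centroid,
            volume = length(m) * grid@edge^3)
    })
    o <- order(vapply(hs, function(h) h@peak, 0), decreasing = TRUE)
    hs <- hs[o]
    for (i in seq_along(hs))
        hs[[i]]@id <- i
    hs
}

#' Write a density grid in OpenDX scalar-field format
#'
#' @param grid A [DensityGrid-class].
#' @param path Output file.
#' @param what `"counts"` (raw hits) or `"sdf"` (normalized density).
#' @return The path, invisibly.
#' @export
writeOpenDX <- function(grid, path, what = c("counts", "sdf")) {
    what <- match.arg(what)
    d <- dim(grid@counts)
    vals <- if (what == "counts") as.numeric(grid@counts)
    else as.numeric(densityValues(grid))
    ## OpenDX stores with the last index varying fastest
    vals <- as.numeric(aperm(array(vals, d), c(1, 2, 3))[
        cbind(rep(1:d[1], each = d[2] * d[3]),
              rep(rep(1:d[2], each = d[3]), d[1]),
              rep(1:d[3], d[1] * d[2]))])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                       d[1], d[2], d[3]), con)
    writeLines(sprintf("origin %.4f %.4f %.4f",
                       grid@origin[1] + grid@edge / 2,
                       grid@origin[2] + grid@edge / 2,
                       grid@origin[3] + grid@edge / 2), con)
    writeLines(sprintf("delta %.4f 0 0", grid@edge), con)
    writeLines(sprintf("delta 0 %.4f 0", grid@edge), con)
    writeLines(sprintf("delta 0 0 %.4f", grid@edge), con)
    writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                       d[1], d[2], d[3]), con)
    writeLines(sprintf("object 3 class array type double rank 0 items %d data follows",
                       prod(d)), con)
    full <- length(vals) %/% 3L
    if (full)
        writeLines(sprintf("%g %g %g",
                           vals[seq_len(full) * 3 - 2],
                           vals[seq_len(full) * 3 - 1],
                           vals[seq_len(full) * 3]), con)
    rest <- length(vals) - full * 3L
    if (rest)
        writeLines(paste(sprintf("%g", vals[full * 3 + seq_len(rest)]),
                         collapse = " "), con)
    writeLines('attribute "dep" string "positions"', con)
    writeLines('object "density" class field', con)
    writeLines('component "positions" value 1', con)
    writeLines('component "connections" value 2', con)
    writeLines('component "data" value 3', con)
    invisible(path)
}
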