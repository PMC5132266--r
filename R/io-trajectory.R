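#' Read a multi-frame coordinate trajectory
#'
#' Supports multi-frame GRO (mandatory path), multi-model PDB, and DCD
#' via the same contract.  Frame times are taken from `t=` tags in GRO
#' title lines when present; otherwise uniform spacing `dt` must be
#' supplied.  The first `discardInitial` nanoseconds are dropped
#' (equilibration discard).
#'
#' @param path File path (`.gro`, `.pdb` or `.dcd`).
#' @param topology The matching [BeadTopology-class]; frame bead counts
#'   are checked against it.
#' @param discardInitial Equilibration time to discard, in ns
#'   (frames with time < `discardInitial` are dropped).
#' @param dt Frame interval in ns; required when the file carries no
#'   time information or when spacing is non-uniform.
#' @param dialect Force `"gro"`, `"pdb"` or `"dcd"`; default from the
#'   extension.
#' @param box Length-3 box lengths in Angstrom, required for formats
#'   without per-frame box records (PDB without CRYST1, DCD).
#' @return A [Trajectory-class].
#' @export
readTrajectory <- function(path, topology, discardInitial = 0, dt = NULL,
                           dialect = NULL, box = NULL) {
    if (!file.exists(path))
        stop(sprintf("file '%s' does not exist", path))
    if (discardInitial < 0)
        stop("discardInitial must be >= 0")
    if (is.null(dialect)) {
        dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb"
        else if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd"
        else "gro"
    }
    dialect <- match.arg(dialect, c("gro", "pdb", "dcd"))
    if (dialect == "gro") {
        lines <- readLines(path)
        frames <- list(); boxes <- list(); times <- numeric()
        at <- 1L
        while (at <= length(lines)) {
            if (!nzchar(trimws(lines[at]))) {
                at <- at + 1L
                next
            }
            fr <- .parseGroFrame(lines, at, path)
            if (is.null(fr)) break
            frames[[length(frames) + 1L]] <- fr$coords
            boxes[[length(boxes) + 1L]] <- fr$box
            times <- c(times, fr$time)
            at <- fr$nextAt
        }
        if (!length(frames))
            stop(sprintf("format error in '%s': no frames found", path))
        nb <- vapply(frames, nrow, 0L)
        if (any(nb != nBeads(topology)))
            stop(sprintf("topology mismatch: trajectory frame has %d beads, topology %d",
                         nb[which(nb != nBeads(topology))[1]], nBeads(topology)))
        coords <- array(0, dim = c(length(frames), nb[1], 3))
        for (i in seq_along(frames))
            coords[i, , ] <- frames[[i]]
        boxm <- do.call(rbind, boxes)
    } else if (dialect == "pdb") {
        pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
        xyz <- pdb$xyz
        if (is.null(dim(xyz)))
            xyz <- matrix(xyz, nrow = 1)
        nb <- ncol(xyz) / 3
        if (nb != nBeads(topology))
            stop(sprintf("topology mismatch: trajectory frame has %d beads, topology %d",
                         nb, nBeads(topology)))
        nf <- nrow(xyz)
        coords <- array(0, dim = c(nf, nb, 3))
        for (i in seq_len(nf))
            coords[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
        if (is.null(box)) {
            cr <- grep("^CRYST1", readLines(path), value = TRUE)
            if (length(cr))
                box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                    substr(cr[1], 25, 33)))
            else
                stop("PDB trajectory without CRYST1: supply 'box'")
        }
        boxm <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
        times <- rep(NA_real_, nf)
    } else {
        xyz <- bio3d::read.dcd(path, verbose = FALSE)
        nb <- ncol(xyz) / 3
        if (nb != nBeads(topology))
            stop(sprintf("topology mismatch: trajectory frame has %d beads, topology %d",
                         nb, nBeads(topology)))
        nf <- nrow(xyz)
        coords <- array(0, dim = c(nf, nb, 3))
        for (i in seq_len(nf))
            coords[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
        if (is.null(box))
            stop("DCD trajectories require an explicit 'box'")
        boxm <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
        times <- rep(NA_real_, nf)
    }

    nf <- dim(coords)[1]
    if (all(is.na(times))) {
        if (is.null(dt))
            stop("no frame times in file: supply 'dt'")
        times <- (seq_len(nf) - 1) * dt
    } else if (anyNA(times)) {
        stop(sprintf("format error in '%s': frame times present only for some frames", path))
    } else {
        dts <- diff(times)
        if (nf > 1L && length(unique(round(dts, 9))) > 1L) {
            if (is.null(dt))
                stop("non-uniform frame spacing: supply 'dt' explicitly")
            times <- (seq_len(nf) - 1) * dt
        } else if (is.null(dt)) {
            dt <- if (nf > 1L) dts[1] else 1
        }
    }
    if (is.null(dt) || dt <= 0)
        stop("dt must be positive")

    keep <- which(times >= discardInitial)
    if (!length(keep))
        stop("empty trajectory: discardInitial exceeds the total simulated time")
    new("Trajectory",
        coords = coords[keep, , , drop = FALSE],
        dt = dt,
        box = boxm[keep, , drop = FALSE],
        times = times[keep])
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param traj A [Trajectory-class].
#' @param topology The matching [BeadTopology-class].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeTrajectoryGRO <- function(traj, topology, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nFrames(traj))) {
        .writeGroFrame(con, topology, beadCoords(traj, i),
                       boxLengths(traj, i),
                       sprintf("cholmap frame %d t= %.4f", i, traj@times[i]))
    }
    invisible(path)
}
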