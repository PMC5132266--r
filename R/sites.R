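## Site assembly and site-based kinetics.

#' Assemble interaction sites by matching outliers to reproducible hotspots
#'
#' Hotspots from the per-system density maps are first grouped across
#' systems by centroid proximity; only groups represented in every
#' system ("entirely reproducible" hotspots) seed sites.  An outlier
#' residue matches a hotspot group if any of its beads lies within
#' `matchRadius` of a super-contour voxel center.  The site is the set
#' of matched outliers plus all masked residues within `matchRadius` of
#' the hotspot; sites are ranked by number of matched outliers, then by
#' peak density.  Groups without any matched outlier are returned as
#' density-only candidates (`ranked = FALSE`) rather than dropped.
#'
#' @param outlierIds Integer residue ids flagged as t_max outliers
#'   (from the merged population).
#' @param hotspotsPerSystem Named list (one element per system) of
#'   [Hotspot-class] lists from [extractHotspots()].
#' @param topology A [BeadTopology-class].
#' @param referenceCoords Beads x 3 reference coordinates (the frame
#'   the densities were fitted to).
#' @param matchRadius Outlier/residue membership radius in Angstrom
#'   (default 6, re-using the contact cutoff).
#' @param groupRadius Centroid distance for matching hotspots across
#'   systems (default 6 Angstrom).
#' @param residueMask Residues eligible for site membership; default
#'   membrane-facing.
#' @return A list with `sites` (ranked [InteractionSite-class]s, then
#'   unranked candidates), and `nonReproducible` (data.frame of hotspot
#'   groups not present in every system).
#' @export
matchOutliersToHotspots <- function(outlierIds, hotspotsPerSystem,
                                    topology, referenceCoords,
                                    matchRadius = 6, groupRadius = 6,
                                    residueMask = NULL) {
    stopifnot(length(hotspotsPerSystem) >= 1L)
    if (is.null(names(hotspotsPerSystem)))
        names(hotspotsPerSystem) <- paste0("SYS", seq_along(hotspotsPerSystem))
    if (is.null(residueMask))
        residueMask <- membraneFacing(topology)
    systems <- names(hotspotsPerSystem)
    cat0 <- do.call(rbind, lapply(systems, function(s) {
        hs <- hotspotsPerSystem[[s]]
        if (!length(hs))
            return(NULL)
        data.frame(system = s, idx = seq_along(hs),
                   x = vapply(hs, function(h) h@centroid[1], 0),
                   y = vapply(hs, function(h) h@centroid[2], 0),
                   z = vapply(hs, function(h) h@centroid[3], 0),
                   peak = vapply(hs, function(h) h@peak, 0),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(cat0) || !nrow(cat0))
        return(list(sites = list(),
                    nonReproducible = data.frame(group = integer(),
                                                 systems = character())))
    ## greedy single-linkage grouping seeded by decreasing peak
    cat0 <- cat0[order(-cat0$peak), ]
    group <- rep(NA_integer_, nrow(cat0))
    g <- 0L
    for (i in seq_len(nrow(cat0))) {
        if (!is.na(group[i]))
            next
        g <- g + 1L
        group[i] <- g
        repeat {
            inG <- which(group == g)
            cand <- which(is.na(group))
            if (!length(cand))
                break
            dd <- outer(inG, cand, function(a, b) {
                sqrt((cat0$x[a] - cat0$x[b])^2 + (cat0$y[a] - cat0$y[b])^2 +
                     (cat0$z[a] - cat0$z[b])^2)
            })
            hitC <- cand[apply(dd <= groupRadius, 2, any)]
            if (!length(hitC))
                break
            group[hitC] <- g
        }
    }
    cat0$group <- group

    maskBeads <- lapply(residueMask,
                        function(r) referenceCoords[residueBeads(topology, r),
                                                    , drop = FALSE])
    names(maskBeads) <- residueMask

    sites <- list()
    nonRep <- list()
    for (gg in unique(cat0$group)) {
        sub <- cat0[cat0$group == gg, ]
        covered <- unique(sub$system)
        if (!all(systems %in% covered)) {
            nonRep[[length(nonRep) + 1L]] <-
                data.frame(group = gg,
                           systems = paste(sort(covered), collapse = "+"),
                           peak = max(sub$peak))
            next
        }
        centers <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
            hotspotsPerSystem[[sub$system[i]]][[sub$idx[i]]]@centers
        }))
        memberIds <- residueMask[vapply(as.character(residueMask), function(r) {
            b <- maskBeads[[r]]
            any(.minCrossDistanceFree(b, centers) <= matchRadius)
        }, TRUE)]
        outl <- intersect(outlierIds, memberIds)
        w <- as.numeric(sub$peak)
        centroid <- c(sum(sub$x * w), sum(sub$y * w), sum(sub$z * w)) / sum(w)
        sites[[length(sites) + 1L]] <-
            new("InteractionSite", name = NA_character_,
                residueIds = as.integer(sort(memberIds)),
                outlierIds = as.integer(sort(outl)),
                hotspotIds = paste(sub$system, sub$idx, sep = ":"),
                topologyClass = NA_character_,
                nBindingModes = NA_integer_,
                peakDensity = max(sub$peak),
                centroid = centroid,
                voxelCenters = centers,
                ranked = length(outl) > 0L)
    }
    if (length(sites)) {
        nOut <- vapply(sites, function(s) length(s@outlierIds), 0L)
        peak <- vapply(sites, function(s) s@peakDensity, 0)
        o <- order(-(nOut > 0), -nOut, -peak)
        sites <- sites[o]
        ranked <- which(vapply(sites, function(s) s@ranked, TRUE))
        unranked <- which(!vapply(sites, function(s) s@ranked, TRUE))
        for (i in seq_along(ranked))
            sites[[ranked[i]]]@name <- paste0("S", i)
        for (i in seq_along(unranked))
            sites[[unranked[i]]]@name <- paste0("C", i)
    }
    list(sites = sites,
         nonReproducible = if (length(nonRep)) do.call(rbind, nonRep)
         else data.frame(group = integer(), systems = character(),
                         peak = numeric()))
}

## min distance between two coordinate sets without PBC
.minCrossDistanceFree <- function(xa, xb) {
    xa <- matrix(xa, ncol = 3)
    xb <- matrix(xb, ncol = 3)
    vapply(seq_len(nrow(xa)), function(i) {
        d <- sweep(xb, 2, xa[i, ])
        sqrt(min(rowSums(d * d)))
    }, 0)
}

#' Classify the topology of a site as linear or non-linear
#'
#' A linear site is defined purely by the protein sequence: all
#' residues fall in one structural segment (helix) and span at most
#' `window` consecutive sequence positions.  Everything else is a
#' three-dimensional, non-linear pocket formed by multiple segments.
#'
#' @param site An [InteractionSite-class].
#' @param segmentMap Named vector: residue id -> segment label.
#' @param sequencePositions Named numeric vector residue id -> sequence
#'   position; defaults to the residue ids themselves.
#' @param window Maximum sequence span of a linear site (default 10).
#' @return The site with `topologyClass` filled in.
#' @export
classifyTopology <- function(site, segmentMap, sequencePositions = NULL,
                             window = 10L) {
    ids <- as.character(site@residueIds)
    if (!all(ids %in% names(segmentMap)))
        stop("unannotated residue(s): ",
             paste(setdiff(ids, names(segmentMap)), collapse = ", "))
    segs <- unique(segmentMap[ids])
    pos <- if (is.null(sequencePositions)) site@residueIds
    else as.numeric(sequencePositions[ids])
    linear <- length(segs) == 1L && (max(pos) - min(pos)) <= window
    site@topologyClass <- if (linear) "linear" else "non-linear"
    site
}

#' Detect binding events from an RMSD series with dual-cutoff hysteresis
#'
#' Three-state logic: a lipid becomes bound when its RMSD from the
#' reference bound pose drops below `boundCutoff`; it remains bound
#' while the RMSD stays at or below `unboundCutoff` (the tolerance that
#' avoids overestimating the unbound state during partial unbinding);
#' it unbinds when the RMSD exceeds `unboundCutoff`.  Event duration is
#' the number of bound frames times `dt`.
#'
#' @param rmsd Numeric per-frame RMSD series in Angstrom (finite).
#' @param boundCutoff Binding threshold (default 6 Angstrom).
#' @param unboundCutoff Complete-unbinding threshold (default 10.8
#'   Angstrom, 1.8 x the binding cutoff).
#' @param dt Frame interval in ns.
#' @return data.frame with `start_frame`, `end_frame` (bound frames,
#'   inclusive), `start_ns`, `end_ns`, `duration_ns`.
#' @export
residenceEvents <- function(rmsd, boundCutoff = 6, unboundCutoff = 10.8,
                            dt = 1) {
    if (unboundCutoff <= boundCutoff)
        stop("unboundCutoff must exceed boundCutoff")
    if (any(!is.finite(rmsd)))
        stop("non-finite RMSD values")
    bound <- FALSE
    start <- NA_integer_
    ev <- list()
    for (i in seq_along(rmsd)) {
        if (!bound) {
            if (rmsd[i] < boundCutoff) {
                bound <- TRUE
                start <- i
            }
        } else if (rmsd[i] > unboundCutoff) {
            ev[[length(ev) + 1L]] <- c(start, i - 1L)
            bound <- FALSE
        }
    }
    if (bound)
        ev[[length(ev) + 1L]] <- c(start, length(rmsd))
    if (!length(ev))
        return(data.frame(start_frame = integer(), end_frame = integer(),
                          start_ns = numeric(), end_ns = numeric(),
                          duration_ns = numeric()))
    m <- do.call(rbind, ev)
    data.frame(start_frame = m[, 1], end_frame = m[, 2],
               start_ns = (m[, 1] - 1) * dt, end_ns = m[, 2] * dt,
               duration_ns = (m[, 2] - m[, 1] + 1) * dt)
}

#' Reference bound pose of a lipid at a site
#'
#' The lipid's fitted-frame coordinates at the frame maximizing the
#' summed site density over its bead positions (density read from the
#' site's member hotspot voxels); ties resolve to the earliest frame.
#'
#' @param lipidCoords Frames x beads x 3 array of the lipid's fitted
#'   coordinates.
#' @param site An [InteractionSite-class] (uses `voxelCenters`).
#' @param grid The [DensityGrid-class] the site's hotspots came from.
#' @return A list with `frame`, `coords` (beads x 3) and `score`; or
#'   NULL when the lipid never overlaps the site's voxels.
#' @export
referenceBoundPose <- function(lipidCoords, site, grid) {
    d <- dim(lipidCoords)
    dims <- dim(grid@counts)
    siteVox <- floor(sweep(site@voxelCenters, 2, grid@origin) / grid@edge) + 1
    siteLin <- unique(siteVox[, 1] + dims[1] * (siteVox[, 2] - 1) +
                      dims[1] * dims[2] * (siteVox[, 3] - 1))
    inSite <- array(FALSE, dim = dims)
    inSite[siteLin] <- TRUE
    scores <- numeric(d[1])
    for (f in seq_len(d[1])) {
        p <- matrix(lipidCoords[f, , ], ncol = 3)
        ix <- floor(sweep(p, 2, grid@origin) / grid@edge) + 1
        ok <- ix[, 1] >= 1 & ix[, 1] <= dims[1] &
            ix[, 2] >= 1 & ix[, 2] <= dims[2] &
            ix[, 3] >= 1 & ix[, 3] <= dims[3]
        if (!any(ok))
            next
        ix <- ix[ok, , drop = FALSE]
        lin <- ix[, 1] + dims[1] * (ix[, 2] - 1) +
            dims[1] * dims[2] * (ix[, 3] - 1)
        use <- inSite[lin]
        if (any(use))
            scores[f] <- sum(grid@counts[lin[use]])
    }
    if (all(scores == 0))
        return(NULL)
    f <- which.max(scores)  # which.max takes the earliest tie
    list(frame = f, coords = matrix(lipidCoords[f, , ], ncol = 3),
         score = scores[f])
}

#' RMSD of a lipid to a reference pose along fitted frames
#'
#' Plain coordinate RMSD (no refitting of the lipid itself): frames are
#' assumed already superposed on the protein reference selection.
#'
#' @param lipidCoords Frames x beads x 3 array.
#' @param pose Beads x 3 reference pose.
#' @return Numeric per-frame RMSD in Angstrom.
#' @export
poseRMSD <- function(lipidCoords, pose) {
    d <- dim(lipidCoords)
    vapply(seq_len(d[1]), function(f) {
        p <- matrix(lipidCoords[f, , ], ncol = 3)
        sqrt(mean(rowSums((p - pose)^2)))
    }, 0)
}

#' Summarize residence events of a site
#'
#' @param eventsByDataset Named list of event data.frames (from
#'   [residenceEvents()], one per data-set, with an added
#'   `molecule_id` column).
#' @param thresholdSpecific Duration separating specific events, in ns
#'   (default 1000, i.e. 1 microsecond).
#' @return One-row data.frame: `max_residence_us`, `n_events_total`,
#'   `n_events_gt_threshold`, `mean_visiting_lipids` (mean number of
#'   distinct molecules with >= 1 event per data-set) and its rounded
#'   report value.
#' @export
summarizeSite <- function(eventsByDataset, thresholdSpecific = 1000) {
    all <- do.call(rbind, lapply(eventsByDataset, function(e) e))
    if (is.null(all) || !nrow(all))
        return(data.frame(max_residence_us = 0, n_events_total = 0L,
                          n_events_gt_threshold = 0L,
                          mean_visiting_lipids = 0,
                          visiting_lipids_report = 0L))
    visiting <- vapply(eventsByDataset, function(e) {
        if (is.null(e) || !nrow(e)) 0L else length(unique(e$molecule_id))
    }, 0L)
    data.frame(max_residence_us = max(all$duration_ns) / 1000,
               n_events_total = nrow(all),
               n_events_gt_threshold = sum(all$duration_ns > thresholdSpecific),
               mean_visiting_lipids = mean(visiting),
               visiting_lipids_report = as.integer(round(mean(visiting))))
}

#' Count distinct binding modes by greedy pose clustering
#'
#' Bound-frame poses are clustered greedily: a pose joins the first
#' cluster whose running centroid is within `clusterRmsd`, otherwise it
#' founds a new cluster.  Modes are clusters holding at least
#' `minFraction` of the bound frames.  When the qualifying modes cover
#' less than half of all poses the count is flagged low confidence
#' (no clustering structure).
#'
#' @param poses Frames x beads x 3 array (or n x k matrix of flattened
#'   poses) of bound-frame lipid coordinates.
#' @param clusterRmsd Cluster radius in Angstrom (default 4).
#' @param minFraction Minimum cluster occupancy to count as a mode
#'   (default 0.05).
#' @return A list with `n_modes`, `sizes` (per-cluster counts) and
#'   `low_confidence`.
#' @export
countBindingModes <- function(poses, clusterRmsd = 4, minFraction = 0.05) {
    if (length(dim(poses)) == 3L) {
        d <- dim(poses)
        poses <- matrix(poses, nrow = d[1])
        nb <- d[2]
    } else {
        nb <- ncol(poses) / 3
    }
    n <- nrow(poses)
    stopifnot(n >= 1L)
    centroids <- poses[1, , drop = FALSE]
    counts <- 1L
    assign <- integer(n)
    assign[1] <- 1L
    if (n > 1L) for (i in 2:n) {
        rms <- sqrt(rowSums(sweep(centroids, 2, poses[i, ])^2) / nb)
        j <- which(rms <= clusterRmsd)
        if (length(j)) {
            j <- j[1]
            ## running mean update keeps centroids stable
            centroids[j, ] <- centroids[j, ] +
                (poses[i, ] - centroids[j, ]) / (counts[j] + 1L)
            counts[j] <- counts[j] + 1L
            assign[i] <- j
        } else {
            centroids <- rbind(centroids, poses[i, ])
            counts <- c(counts, 1L)
            assign[i] <- length(counts)
        }
    }
    qual <- counts / n >= minFraction
    list(n_modes = sum(qual), sizes = counts,
         low_confidence = sum(counts[qual]) / n < 0.5)
}

#' Minimum-distance time series between two bead groups
#'
#' Per frame, the minimum over all cross pairs of (minimum-image)
#' distances; symmetric in the two groups.
#'
#' @param traj A [Trajectory-class].
#' @param groupA,groupB Non-empty bead index vectors.
#' @param pbc Apply minimum image (default TRUE).
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
minDistanceTimeseries <- function(traj, groupA, groupB, pbc = TRUE) {
    stopifnot(length(groupA) > 0, length(groupB) > 0)
    vapply(seq_len(nFrames(traj)), function(f) {
        fr <- beadCoords(traj, f)
        .minCrossDistance(fr[groupA, , drop = FALSE],
                          fr[groupB, , drop = FALSE],
                          boxLengths(traj, f), pbc)
    }, 0)
}

#' Species selectivity (annularity) of an interaction site
#'
#' Compares, per lipid species, the mean t_max over the site residues
#' and the mean normalized density over the site voxels.  A site is
#' non-annular (a pocket effectively inaccessible to lipids other than
#' cholesterol) iff every non-cholesterol species has a mean site
#' density below `fraction` of cholesterol's.
#'
#' @param site An [InteractionSite-class].
#' @param tmaxProfile Output of [speciesTmaxProfile()].
#' @param gridsBySpecies Named list of [DensityGrid-class] per species,
#'   sharing geometry.
#' @param fraction Density fraction defining negligible occupancy
#'   (default 0.1).
#' @param referenceSpecies The species the site is selective for
#'   (default `"CHOL"`).
#' @return A list with `perSpecies` (data.frame `species`,
#'   `mean_tmax_ns`, `mean_density`) and `non_annular` (logical).
#' @export
siteSelectivity <- function(site, tmaxProfile, gridsBySpecies,
                            fraction = 0.1, referenceSpecies = "CHOL") {
    sp <- names(gridsBySpecies)
    stopifnot(referenceSpecies %in% sp)
    g1 <- gridsBySpecies[[1]]
    dims <- dim(g1@counts)
    siteVox <- floor(sweep(site@voxelCenters, 2, g1@origin) / g1@edge) + 1
    lin <- unique(siteVox[, 1] + dims[1] * (siteVox[, 2] - 1) +
                  dims[1] * dims[2] * (siteVox[, 3] - 1))
    per <- do.call(rbind, lapply(sp, function(s) {
        g <- gridsBySpecies[[s]]
        if (!identical(dim(g@counts), dims) ||
            any(abs(g@origin - g1@origin) > 1e-9))
            stop("grids must share geometry")
        tm <- tmaxProfile[tmaxProfile$species == s &
                          tmaxProfile$residue_id %in% site@residueIds, ]
        data.frame(species = s,
                   mean_tmax_ns = if (nrow(tm)) mean(tm$mean_tmax_ns) else 0,
                   mean_density = mean(densityValues(g)[lin]),
                   stringsAsFactors = FALSE)
    }))
    ref <- per$mean_density[per$species == referenceSpecies]
    others <- per[per$species != referenceSpecies, ]
    nonAnn <- if (!nrow(others)) NA
    else if (ref == 0) FALSE
    else all(others$mean_density < fraction * ref)
    list(perSpecies = per, non_annular = nonAnn)
}
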