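## Synthetic coarse-grained membrane systems with planted lipid
## interaction sites and known ground truth.
##
## The generator emulates the structure of the simulated data the
## analysis protocol is designed for: a static transmembrane helix
## bundle (two monomers per box), a two-leaflet membrane of laterally
## diffusing lipids (CHOL/PC/PE at a prescribed cholesterol mole
## fraction), and planted surface sites where cholesterol dwells with
## exponential residence times on top of nanosecond background
## contacts.  It makes no attempt at physical realism (no forces, no
## excluded volume): it provides ground truth for parameter recovery.

#' Specification of a synthetic membrane system
#'
#' Defaults encode the reference study conditions used throughout the
#' package validation: a 30 microsecond run sampled every 10 ns (plus a
#' 500 ns equilibration stretch to discard), two monomers of an
#' 8-helix bundle, a 100 x 100 Angstrom bilayer patch at 15-25 mol%
#' cholesterol, and three planted cholesterol sites per monomer with
#' mean dwells of 2, 1 and 0.5 microseconds against ~10 ns background
#' contacts.
#'
#' @param box Box lengths (x, y, z) in Angstrom.
#' @param nFrames Number of frames to generate.
#' @param dt Frame interval in ns.
#' @param cholFraction Cholesterol mole fraction in (0, 1); the
#'   remainder is split evenly between PC and PE.
#' @param lipidCounts Optional named integer vector (`CHOL`, `PC`,
#'   `PE`) overriding the fraction-derived counts.
#' @param areaPerLipid Membrane area per lipid in Angstrom^2
#'   (default 65, a typical coarse-grained value).
#' @param nHelices,residuesPerHelix,beadsPerResidue,bundleRadius
#'   Protein geometry; helices stand vertically on a circle of radius
#'   `bundleRadius` (Angstrom).
#' @param nMonomers Number of protein monomers (independent
#'   data-sets) per box.
#' @param diffusion Named per-species lateral diffusion coefficients
#'   in Angstrom^2/ns.
#' @param diffusionCholSlope Fractional slow-down of all diffusion
#'   coefficients per unit cholesterol fraction above 0.15 (diffusion
#'   decreases as cholesterol enriches).
#' @param plantedSites List of sites, each a list with `helices`
#'   (two adjacent helix indices), `meanDwell` (ns), `captureRadius`
#'   (Angstrom), `bindProb` (binding probability per encounter), and
#'   optionally `species` (default `"CHOL"`).  `NULL` disables
#'   planting; the default plants three sites with dwells 2000, 1000
#'   and 500 ns.
#' @param proteinJitter Per-frame Gaussian jitter of protein beads
#'   (Angstrom).
#' @param boundJitter Positional jitter of a bound lipid around its
#'   site anchor (Angstrom).
#' @param seed Integer seed; a single RNG stream drives all
#'   randomness, so equal seeds give identical trajectories.
#' @return A validated list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(box = c(100, 100, 80),
                          nFrames = 3050L, dt = 10,
                          cholFraction = 0.25,
                          lipidCounts = NULL,
                          areaPerLipid = 65,
                          nHelices = 8L, residuesPerHelix = 6L,
                          beadsPerResidue = 1L, bundleRadius = 12,
                          nMonomers = 2L,
                          diffusion = c(CHOL = 4, PC = 2, PE = 2),
                          diffusionCholSlope = 1.5,
                          plantedSites = defaultPlantedSites(),
                          proteinJitter = 0.3,
                          boundJitter = 0.3,
                          seed = 1L) {
    spec <- list(box = box, nFrames = as.integer(nFrames), dt = dt,
                 cholFraction = cholFraction, lipidCounts = lipidCounts,
                 areaPerLipid = areaPerLipid,
                 nHelices = as.integer(nHelices),
                 residuesPerHelix = as.integer(residuesPerHelix),
                 beadsPerResidue = as.integer(beadsPerResidue),
                 bundleRadius = bundleRadius,
                 nMonomers = as.integer(nMonomers),
                 diffusion = diffusion,
                 diffusionCholSlope = diffusionCholSlope,
                 plantedSites = plantedSites,
                 proteinJitter = proteinJitter,
                 boundJitter = boundJitter,
                 seed = as.integer(seed))
    class(spec) <- "SyntheticSpec"
    validateSyntheticSpec(spec)
    spec
}

#' Default planted sites: dwells of 2, 1 and 0.5 microseconds
#'
#' @param contactCutoff Cutoff used only to flag capture radii larger
#'   than the contact cutoff (allowed, but worth knowing).
#' @return List of site definitions for [syntheticSpec()].
#' @export
defaultPlantedSites <- function(contactCutoff = 6) {
    list(list(name = "P1", helices = c(1L, 2L), meanDwell = 2000,
              captureRadius = 8, bindProb = 0.5, species = "CHOL"),
         list(name = "P2", helices = c(4L, 5L), meanDwell = 1000,
              captureRadius = 8, bindProb = 0.5, species = "CHOL"),
         list(name = "P3", helices = c(7L, 8L), meanDwell = 500,
              captureRadius = 8, bindProb = 0.5, species = "CHOL"))
}

#' Validate a synthetic system specification
#'
#' @param spec A `"SyntheticSpec"` list.
#' @return TRUE invisibly; stops on invalid specifications.
#' @export
validateSyntheticSpec <- function(spec) {
    stopifnot(length(spec$box) == 3L, all(spec$box > 0),
              spec$nFrames >= 2L, spec$dt > 0,
              spec$nHelices >= 1L, spec$residuesPerHelix >= 1L,
              spec$nMonomers >= 1L)
    if (spec$cholFraction <= 0 || spec$cholFraction >= 1)
        stop("cholFraction must be in (0, 1)")
    counts <- .lipidCounts(spec)
    if (sum(counts) * 50 > 2 * spec$box[1] * spec$box[2])
        stop("packing error: lipid area exceeds the available membrane area")
    for (s in spec$plantedSites) {
        if (is.null(s$meanDwell) || s$meanDwell <= 0)
            stop("planted site meanDwell must be positive")
        if (!is.null(s$captureRadius) && s$captureRadius > 6)
            message(sprintf("note: site %s capture radius %.1f A exceeds the 6 A contact cutoff",
                            if (is.null(s$name)) "?" else s$name,
                            s$captureRadius))
        if (is.null(s$helices) || length(s$helices) != 2L)
            stop("planted sites need two helix indices")
    }
    invisible(TRUE)
}

## species counts from the cholesterol fraction (remainder split PC/PE)
.lipidCounts <- function(spec) {
    if (!is.null(spec$lipidCounts)) {
        counts <- spec$lipidCounts[c("CHOL", "PC", "PE")]
        counts[is.na(counts)] <- 0L
        names(counts) <- c("CHOL", "PC", "PE")
        return(counts)
    }
    n <- 2L * round(spec$box[1] * spec$box[2] / spec$areaPerLipid)
    nChol <- round(spec$cholFraction * n)
    nPC <- round((n - nChol) / 2)
    c(CHOL = nChol, PC = nPC, PE = n - nChol - nPC)
}

#' Generate a synthetic membrane system with planted sites
#'
#' Builds the bead topology, simulates the trajectory (static jittered
#' protein; lipids performing 2-D lateral Brownian motion in their
#' leaflet; cholesterol binding at planted sites with exponential
#' dwells), and returns the full ground truth of planted binding
#' intervals.
#'
#' @param spec A [syntheticSpec()].
#' @return A list with `topology` ([BeadTopology-class]),
#'   `trajectory` ([Trajectory-class]), `groundTruth` (list with
#'   `sites` and `events` data.frames), and `spec`.
#' @export
generateSystem <- function(spec) {
    validateSyntheticSpec(spec)
    set.seed(spec$seed)
    box <- spec$box
    zc <- box[3] / 2
    leafZ <- c(upper = zc + 10, lower = zc - 10)
    levels <- seq(-22, 18, length.out = spec$residuesPerHelix)

    ## --- protein -------------------------------------------------------
    monoCentersX <- box[1] * (seq_len(spec$nMonomers) - 0.5) / spec$nMonomers
    nResPerMono <- spec$nHelices * spec$residuesPerHelix
    resList <- list()
    beadPos <- list()
    beadOwner <- list()
    rid <- 0L
    aaPalette <- c("ALA", "GLY", "SER", "THR", "ILE", "MET", "ASN", "GLN",
                   "GLU", "ASP", "HIS", "PRO", "CYS", "TRP")
    for (m in seq_len(spec$nMonomers)) {
        mono <- LETTERS[m]
        for (h in seq_len(spec$nHelices)) {
            th <- 2 * pi * (h - 1) / spec$nHelices
            for (l in seq_len(spec$residuesPerHelix)) {
                rid <- rid + 1L
                base <- c(monoCentersX[m] + spec$bundleRadius * cos(th),
                          box[2] / 2 + spec$bundleRadius * sin(th),
                          zc + levels[l])
                for (b in seq_len(spec$beadsPerResidue)) {
                    p <- base
                    if (b > 1L) {
                        p[1] <- p[1] + 2.4 * (b - 1) * cos(th)
                        p[2] <- p[2] + 2.4 * (b - 1) * sin(th)
                    }
                    beadPos[[length(beadPos) + 1L]] <- p
                    beadOwner[[length(beadOwner) + 1L]] <- c("residue", rid)
                }
                resList[[rid]] <- data.frame(
                    residue_id = rid,
                    name = sample(aaPalette, 1L),
                    monomer = mono,
                    membrane_facing = TRUE,
                    helix = h, level = l,
                    stringsAsFactors = FALSE)
            }
        }
    }
    resDf <- do.call(rbind, resList)
    resDf$resid_orig <- resDf$residue_id
    resDf$seq_pos <- stats::ave(resDf$residue_id, resDf$monomer,
                                FUN = seq_along)

    ## --- lipids --------------------------------------------------------
    counts <- .lipidCounts(spec)
    lipNames <- c(CHOL = "CHOL", PC = "DSPC", PE = "POPE")
    speciesVec <- rep(names(counts), counts)
    nLip <- length(speciesVec)
    leaflet <- unlist(lapply(counts, function(k)
        rep(c("upper", "lower"), length.out = k)), use.names = FALSE)
    lipDf <- data.frame(molecule_id = seq_len(nLip), species = speciesVec,
                        name = unname(lipNames[speciesVec]),
                        leaflet = leaflet, stringsAsFactors = FALSE)
    for (i in seq_len(nLip)) {
        beadPos[[length(beadPos) + 1L]] <-
            c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
              unname(leafZ[leaflet[i]]))
        beadOwner[[length(beadOwner) + 1L]] <- c("lipid", i)
    }
    nProtBeads <- sum(resDf$residue_id > 0) * spec$beadsPerResidue
    own <- do.call(rbind, beadOwner)
    beads <- data.frame(index = seq_len(nrow(own)), owner = own[, 1],
                        owner_id = as.integer(own[, 2]),
                        name = ifelse(own[, 1] == "residue", "BB", "L1"),
                        stringsAsFactors = FALSE)
    topo <- new("BeadTopology", residues = resDf, lipids = lipDf,
                beads = beads, nBeads = nrow(beads))

    ## --- planted site geometry ----------------------------------------
    sites <- list()
    if (length(spec$plantedSites)) {
        for (m in seq_len(spec$nMonomers)) {
            for (si in seq_along(spec$plantedSites)) {
                s <- spec$plantedSites[[si]]
                h1 <- s$helices[1]; h2 <- s$helices[2]
                thm <- pi * ((h1 - 1) + (h2 - 1)) / spec$nHelices
                lvl <- which.min(abs(levels - 10))  # leaflet-level residues
                anchor <- c(monoCentersX[m] +
                            (spec$bundleRadius + 1) * cos(thm),
                            box[2] / 2 + (spec$bundleRadius + 1) * sin(thm),
                            unname(leafZ["upper"]))
                resIds <- resDf$residue_id[resDf$monomer == LETTERS[m] &
                                           resDf$helix %in% c(h1, h2) &
                                           resDf$level == lvl]
                sites[[length(sites) + 1L]] <- list(
                    name = if (is.null(s$name)) paste0("P", si) else s$name,
                    monomer = LETTERS[m],
                    anchor = anchor,
                    residues = resIds,
                    meanDwell = s$meanDwell,
                    captureRadius = if (is.null(s$captureRadius)) 8
                                    else s$captureRadius,
                    bindProb = if (is.null(s$bindProb)) 0.5 else s$bindProb,
                    species = if (is.null(s$species)) "CHOL" else s$species,
                    leaflet = "upper")
            }
        }
    }

    ## --- dynamics ------------------------------------------------------
    dSlow <- max(0.1, 1 - spec$diffusionCholSlope *
                          max(0, spec$cholFraction - 0.15))
    dEff <- spec$diffusion * dSlow
    sigma <- sqrt(2 * dEff * spec$dt)  # per-axis lateral step
    sigLip <- unname(sigma[speciesVec])

    protBase <- do.call(rbind, beadPos[seq_len(nProtBeads)])
    lipPos <- do.call(rbind, beadPos[nProtBeads + seq_len(nLip)])

    nb <- nrow(own)
    coords <- array(0, dim = c(spec$nFrames, nb, 3))
    boxm <- matrix(box, nrow = spec$nFrames, ncol = 3, byrow = TRUE)

    boundSite <- integer(nLip)        # 0 = free
    dwellLeft <- integer(nLip)
    refractory <- integer(nLip)
    siteOccupant <- integer(length(sites))
    evSite <- character(); evMono <- character(); evMol <- integer()
    evStart <- integer(); evEnd <- integer()
    openStart <- integer(nLip)

    for (f in seq_len(spec$nFrames)) {
        prot <- protBase +
            matrix(stats::rnorm(nProtBeads * 3, sd = spec$proteinJitter),
                   ncol = 3)
        ## free lipids diffuse laterally
        free <- boundSite == 0L
        nf <- sum(free)
        if (nf) {
            lipPos[free, 1] <- (lipPos[free, 1] +
                stats::rnorm(nf, sd = sigLip[free])) %% box[1]
            lipPos[free, 2] <- (lipPos[free, 2] +
                stats::rnorm(nf, sd = sigLip[free])) %% box[2]
        }
        refractory[refractory > 0L] <- refractory[refractory > 0L] - 1L
        ## capture at free sites
        for (k in seq_along(sites)) {
            if (siteOccupant[k] != 0L)
                next
            s <- sites[[k]]
            cand <- which(boundSite == 0L & refractory == 0L &
                          lipDf$species == s$species &
                          lipDf$leaflet == s$leaflet)
            if (!length(cand))
                next
            dx <- abs(lipPos[cand, 1] - s$anchor[1])
            dx <- pmin(dx, box[1] - dx)
            dy <- abs(lipPos[cand, 2] - s$anchor[2])
            dy <- pmin(dy, box[2] - dy)
            near <- cand[dx * dx + dy * dy <= s$captureRadius^2]
            for (i in near) {
                if (stats::runif(1) < s$bindProb) {
                    boundSite[i] <- k
                    siteOccupant[k] <- i
                    dwellLeft[i] <- max(1L, as.integer(round(
                        stats::rexp(1, 1 / s$meanDwell) / spec$dt)))
                    openStart[i] <- f
                    break
                }
            }
        }
        ## bound lipids sit at their anchor
        bnd <- which(boundSite > 0L)
        for (i in bnd) {
            s <- sites[[boundSite[i]]]
            lipPos[i, ] <- s$anchor + stats::rnorm(3, sd = spec$boundJitter)
        }
        coords[f, seq_len(nProtBeads), ] <- prot
        coords[f, nProtBeads + seq_len(nLip), ] <- lipPos
        ## releases happen after the frame is recorded
        for (i in bnd) {
            dwellLeft[i] <- dwellLeft[i] - 1L
            if (dwellLeft[i] <= 0L) {
                k <- boundSite[i]
                s <- sites[[k]]
                evSite <- c(evSite, s$name); evMono <- c(evMono, s$monomer)
                evMol <- c(evMol, i)
                evStart <- c(evStart, openStart[i]); evEnd <- c(evEnd, f)
                phi <- stats::runif(1, 0, 2 * pi)
                lipPos[i, 1] <- (s$anchor[1] + 14 * cos(phi)) %% box[1]
                lipPos[i, 2] <- (s$anchor[2] + 14 * sin(phi)) %% box[2]
                lipPos[i, 3] <- unname(leafZ[lipDf$leaflet[i]])
                boundSite[i] <- 0L
                siteOccupant[k] <- 0L
                refractory[i] <- 5L
            }
        }
    }
    ## close intervals still open at the final frame
    for (i in which(boundSite > 0L)) {
        s <- sites[[boundSite[i]]]
        evSite <- c(evSite, s$name); evMono <- c(evMono, s$monomer)
        evMol <- c(evMol, i)
        evStart <- c(evStart, openStart[i]); evEnd <- c(evEnd, spec$nFrames)
    }

    traj <- new("Trajectory", coords = coords, dt = spec$dt, box = boxm,
                times = (seq_len(spec$nFrames) - 1) * spec$dt)
    gtSites <- if (length(sites)) data.frame(
        site = vapply(sites, `[[`, "", "name"),
        monomer = vapply(sites, `[[`, "", "monomer"),
        mean_dwell_ns = vapply(sites, `[[`, 0, "meanDwell"),
        capture_radius = vapply(sites, `[[`, 0, "captureRadius"),
        anchor_x = vapply(sites, function(s) s$anchor[1], 0),
        anchor_y = vapply(sites, function(s) s$anchor[2], 0),
        anchor_z = vapply(sites, function(s) s$anchor[3], 0),
        residues = vapply(sites, function(s)
            paste(s$residues, collapse = ","), ""),
        stringsAsFactors = FALSE)
    else data.frame()
    gtEvents <- data.frame(site = evSite, monomer = evMono,
                           molecule_id = evMol, start_frame = evStart,
                           end_frame = evEnd,
                           duration_ns = (evEnd - evStart + 1L) * spec$dt,
                           stringsAsFactors = FALSE)
    list(topology = topo, trajectory = traj,
         groundTruth = list(sites = gtSites, events = gtEvents),
         spec = spec)
}

#' Write a synthetic system as a re-readable fixture
#'
#' Emits a GRO topology (first frame), a multi-frame GRO trajectory,
#' sidecar files (monomer labels, membrane-facing residues, species
#' map) and the ground truth / spec as JSON, so the system can be read
#' back through [readTopology()] and [readTrajectory()].
#'
#' @param system Output of [generateSystem()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(system, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop(sprintf("cannot create directory '%s'", dir))
    topo <- system$topology
    traj <- system$trajectory
    paths <- c(topology = file.path(dir, "topology.gro"),
               trajectory = file.path(dir, "trajectory.gro"),
               monomers = file.path(dir, "monomers.txt"),
               facing = file.path(dir, "membrane_facing.txt"),
               species = file.path(dir, "species_map.txt"),
               ground_truth = file.path(dir, "ground_truth.json"),
               spec = file.path(dir, "spec.json"))
    writeTopologyGRO(topo, beadCoords(traj, 1L), boxLengths(traj, 1L),
                     paths["topology"], title = "synthetic system t= 0")
    writeTrajectoryGRO(traj, topo, paths["trajectory"])
    res <- residues(topo)
    writeLines(paste(res$residue_id, res$monomer), paths["monomers"])
    writeLines(as.character(membraneFacing(topo)), paths["facing"])
    lip <- lipids(topo)
    map <- unique(lip[, c("name", "species")])
    writeLines(paste(map$name, map$species), paths["species"])
    jsonlite::write_json(system$groundTruth, paths["ground_truth"],
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    sp <- system$spec
    class(sp) <- NULL
    sp$plantedSites <- lapply(sp$plantedSites, function(s) s)
    jsonlite::write_json(sp, paths["spec"], auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(paths)
}

#' Lateral mean-squared displacement of a lipid species
#'
#' Unwraps lipid motion through the periodic boundaries by
#' minimum-image frame increments (valid while per-frame steps are
#' well below half the box) and averages the lateral MSD over
#' molecules and time origins.
#'
#' @param traj A [Trajectory-class].
#' @param topology A [BeadTopology-class].
#' @param species Lipid species.
#' @param maxLag Largest lag (in frames) to evaluate.
#' @param originStride Use every `originStride`-th frame as a time
#'   origin.
#' @return data.frame with `lag_frames`, `lag_ns`, `msd` (Angstrom^2).
#' @export
lateralMSD <- function(traj, topology, species = "CHOL", maxLag = 20L,
                       originStride = 7L) {
    b <- lipidBeads(topology, species = species)
    co <- traj@coords[, b, 1:2, drop = FALSE]
    nf <- dim(co)[1]
    stopifnot(maxLag < nf)
    ## unwrap increments
    nmol <- dim(co)[2]
    for (k in 1:2) {
        x <- matrix(co[, , k], nrow = nf, ncol = nmol)
        inc <- x[-1, , drop = FALSE] - x[-nf, , drop = FALSE]
        bx <- traj@box[-1, k]
        inc <- inc - bx * round(inc / bx)
        co[, , k] <- apply(rbind(x[1, ], inc), 2, cumsum)
    }
    origins <- seq(1L, nf - maxLag, by = originStride)
    msd <- vapply(seq_len(maxLag), function(lag) {
        d1 <- co[origins + lag, , 1, drop = FALSE] -
            co[origins, , 1, drop = FALSE]
        d2 <- co[origins + lag, , 2, drop = FALSE] -
            co[origins, , 2, drop = FALSE]
        mean(d1 * d1 + d2 * d2)
    }, 0)
    data.frame(lag_frames = seq_len(maxLag),
               lag_ns = seq_len(maxLag) * traj@dt, msd = msd)
}
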