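## End-to-end orchestration of the four-step mapping protocol:
## contacts -> t_max statistics -> density maps -> site assembly ->
## residence / selectivity / motifs, with CSV/JSON/OpenDX outputs and a
## reproducible run manifest.

#' Configuration of a protocol run
#'
#' @param contactCutoff Residue-lipid contact cutoff, Angstrom.
#' @param boundCutoff,unboundCutoff Dual RMSD cutoffs of the residence
#'   state machine, Angstrom (bound below 6; completely unbound above
#'   10.8 = 1.8 x 6).
#' @param alpha Significance level of all rank tests.
#' @param voxel Density voxel edge, Angstrom.
#' @param contourLevels Contour levels (hits/voxel) reported for the
#'   density maps.
#' @param siteContour Contour level used to seed sites.
#' @param discardInitial Equilibration time discarded from every
#'   trajectory, ns.
#' @param matchRadius Outlier/residue-to-hotspot membership radius,
#'   Angstrom.
#' @param groupRadius Cross-system hotspot matching radius, Angstrom.
#' @param minVoxels Minimum hotspot size in voxels.
#' @param connectivity Hotspot voxel connectivity (26 or 6).
#' @param gapTolerance Interior gap frames bridged in t_max runs.
#' @param residenceSystems System labels analyzed for residence events
#'   and selectivity; `NULL` = all systems.
#' @param selectivitySpecies Non-reference species compared in the
#'   selectivity analysis.
#' @param thresholdSpecific Duration separating specific residence
#'   events, ns.
#' @param quantileType Quartile convention (see [summarizeTmax()]).
#' @param linearWindow Sequence span of a linear site.
#' @param clusterRmsd Binding-mode cluster radius, Angstrom.
#' @param writeGrids Write OpenDX density grids.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A validated list of class `"RunConfig"`.
#' @export
runConfig <- function(contactCutoff = 6, boundCutoff = 6,
                      unboundCutoff = 10.8, alpha = 0.01, voxel = 1,
                      contourLevels = c(40, 60), siteContour = 40,
                      discardInitial = 500, matchRadius = 6,
                      groupRadius = 6, minVoxels = 5L, connectivity = 26L,
                      gapTolerance = 0L, residenceSystems = NULL,
                      selectivitySpecies = c("PC", "PE"),
                      thresholdSpecific = 1000, quantileType = 7,
                      linearWindow = 10L, clusterRmsd = 4,
                      writeGrids = FALSE, seed = 1L) {
    cfg <- as.list(environment())
    stopifnot(cfg$contactCutoff > 0, cfg$boundCutoff > 0,
              cfg$unboundCutoff > cfg$boundCutoff,
              cfg$alpha > 0, cfg$alpha < 1, cfg$voxel > 0,
              all(cfg$contourLevels > 0), cfg$siteContour > 0,
              cfg$discardInitial >= 0)
    class(cfg) <- "RunConfig"
    cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys match [runConfig()] arguments.
#' @return A `"RunConfig"` list.
#' @export
loadRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    do.call(runConfig, vals)
}

#' Generate a replicated multi-system synthetic study
#'
#' Builds the data-set structure the protocol expects: several
#' membrane systems at increasing cholesterol mole fraction (default
#' 15/20/25 mol%), each simulated in independent replicas with two
#' monomers per box and identical planted sites.
#'
#' @param cholFractions Cholesterol mole fractions, one per system.
#' @param replicas Replicas per system.
#' @param seed Base seed; each replica derives its own stream.
#' @param labels System labels (default `SYS1..SYSk`).
#' @param ... Further arguments to [syntheticSpec()].
#' @return A named list of systems, each a list with `label`,
#'   `cholFraction` and `replicas` (list of [generateSystem()]
#'   outputs).
#' @export
generateStudy <- function(cholFractions = c(0.15, 0.20, 0.25),
                          replicas = 2L, seed = 1L, labels = NULL, ...) {
    if (is.null(labels))
        labels <- paste0("SYS", seq_along(cholFractions))
    systems <- list()
    for (i in seq_along(cholFractions)) {
        reps <- list()
        for (j in seq_len(replicas)) {
            spec <- syntheticSpec(cholFraction = cholFractions[i],
                                  seed = (seed * 97L + i * 13L + j) %% 2147483647L,
                                  ...)
            reps[[j]] <- generateSystem(spec)
        }
        systems[[labels[i]]] <- list(label = labels[i],
                                     cholFraction = cholFractions[i],
                                     replicas = reps)
    }
    systems
}

#' Drop the equilibration stretch of a trajectory
#'
#' @param traj A [Trajectory-class].
#' @param discardInitial Time in ns; frames with time < this are
#'   dropped.
#' @return The trimmed [Trajectory-class].
#' @export
discardEquilibration <- function(traj, discardInitial) {
    keep <- which(traj@times >= discardInitial)
    if (!length(keep))
        stop("empty trajectory: discardInitial exceeds the simulated time")
    traj@coords <- traj@coords[keep, , , drop = FALSE]
    traj@box <- traj@box[keep, , drop = FALSE]
    traj@times <- traj@times[keep]
    traj
}

## map per-monomer residue ids to the monomer-independent sequence
## position (homomeric monomers are the same protein)
.commonIds <- function(topology) {
    res <- residues(topology)
    stats::setNames(res$seq_pos, res$residue_id)
}

#' Run the full site-mapping protocol on a study
#'
#' Executes, in order: per-data-set contact detection and maximum
#' occupancy times (one data-set per replica x monomer); per-system
#' merging by Kruskal-Wallis with leave-one-out; cross-system merging
#' into the single outlier-defining population with Tukey-fence
#' screening; per-system spatial density maps on the merged
#' macro-samples; reproducibility-filtered hotspot extraction; site
#' assembly and topology classification; residence-event, binding-mode
#' and selectivity analysis; and optional motif scanning.  All tables
#' are written as CSV, the sites and a run manifest as JSON.
#'
#' @param study Output of [generateStudy()], or an equivalent list of
#'   systems with `replicas` carrying `topology`/`trajectory`.
#' @param config A [runConfig()].
#' @param outDir Output directory (created); `NULL` skips file output.
#' @param sequenceFasta Optional FASTA file scanned for CRAC/CARC
#'   motifs.
#' @return A report bundle (list) with elements `tmax`,
#'   `datasetSummaries`, `merge`, `outliers`, `grids`, `hotspots`,
#'   `sites`, `siteSummaries`, `events`, `selectivity`, `motifs`,
#'   `manifest`.
#' @export
runProtocol <- function(study, config = runConfig(), outDir = NULL,
                        sequenceFasta = NULL) {
    stopifnot(length(study) >= 1L)
    sysLabels <- names(study)
    if (is.null(sysLabels))
        stop("study systems must be named")

    ## reference frame: first replica of the first system
    refTopo <- study[[1]]$replicas[[1]]$topology
    refMono <- monomerLabels(refTopo)[1]
    refTraj0 <- discardEquilibration(study[[1]]$replicas[[1]]$trajectory,
                                     config$discardInitial)
    referenceCoords <- beadCoords(refTraj0, 1L)
    refFacing <- intersect(membraneFacing(refTopo),
                           monomerResidues(refTopo, refMono))
    refBeads <- residueBeads(refTopo, refFacing)
    pb <- referenceCoords[residueBeads(refTopo,
                                       monomerResidues(refTopo, refMono)),
                          , drop = FALSE]
    gridGeom <- list(origin = floor(apply(pb, 2, min) - 15),
                     dims = as.integer(ceiling((ceiling(apply(pb, 2, max) + 15) -
                                                floor(apply(pb, 2, min) - 15)) /
                                               config$voxel)))

    allSpecies <- unique(unlist(lapply(study, function(s)
        lipids(s$replicas[[1]]$topology)$species)))
    binSpecies <- intersect(c("CHOL", config$selectivitySpecies), allSpecies)

    tmaxAll <- list()
    gridsBySystem <- list()     # merged CHOL grid per system
    gridsSpecies <- list()      # per species, list of per-dataset grids
    contactsByDataset <- list()
    datasetMeta <- list()
    fittedCache <- list()       # superposed trajectories, reused for kinetics

    for (s in sysLabels) {
        sys <- study[[s]]
        perSpGrids <- stats::setNames(vector("list", length(binSpecies)),
                                      binSpecies)
        for (r in seq_along(sys$replicas)) {
            rep <- sys$replicas[[r]]
            topo <- rep$topology
            traj <- discardEquilibration(rep$trajectory,
                                         config$discardInitial)
            monos <- monomerLabels(topo)
            commonIds <- .commonIds(topo)
            ## contacts per monomer data-set (all species at once)
            for (mi in seq_along(monos)) {
                m <- monos[mi]
                label <- sprintf("%s.%d%s", s, r, letters[mi])
                mask <- intersect(membraneFacing(topo),
                                  monomerResidues(topo, m))
                cr <- detectContacts(traj, topo,
                                     cutoff = config$contactCutoff,
                                     species = binSpecies,
                                     residueMask = mask)
                tm <- computeTmax(cr, gapTolerance = config$gapTolerance,
                                  label = label, species = binSpecies)
                tm$system <- s
                tm$common_id <- unname(commonIds[as.character(tm$residue_id)])
                tmaxAll[[label]] <- tm
                contactsByDataset[[label]] <- cr
                datasetMeta[[label]] <-
                    list(system = s, replica = r, monomer = m,
                         lengthNs = nFrames(traj) * frameInterval(traj))
                ## superpose once per data-set, then bin every species
                selBeads <- residueBeads(topo, mask)
                ftTraj <- fitTrajectory(traj, reference = referenceCoords,
                                        selection = selBeads,
                                        refSelection = refBeads)$trajectory
                fittedCache[[label]] <- ftTraj
                for (sp in binSpecies) {
                    g <- computeSDF(ftTraj, topo, species = sp,
                                    voxel = config$voxel,
                                    grid = gridGeom, fit = FALSE)
                    perSpGrids[[sp]][[label]] <- g
                }
            }
        }
        gridsSpecies[[s]] <- perSpGrids
    }
    tmaxDf <- do.call(rbind, tmaxAll)
    rownames(tmaxDf) <- NULL

    ## ---- statistics: per-system merge, cross-system merge, outliers ----
    cholByDataset <- split(tmaxDf[tmaxDf$species == "CHOL", ],
                           tmaxDf$dataset[tmaxDf$species == "CHOL"])
    datasetSummaries <- do.call(rbind, lapply(names(cholByDataset),
        function(l) {
            v <- cholByDataset[[l]]
            s <- summarizeTmax(v$tmax_ns[v$contacting], label = l,
                               quantileType = config$quantileType)
            s$system <- v$system[1]
            s
        }))

    systemMerges <- list()
    macroValues <- list()
    macroIds <- list()
    for (s in sysLabels) {
        labs <- names(Filter(function(m) m$system == s, datasetMeta))
        vals <- lapply(labs, function(l) {
            v <- cholByDataset[[l]]
            v$tmax_ns[v$contacting]
        })
        names(vals) <- labs
        mg <- if (length(vals) >= 2L) {
            leaveOneOutMerge(vals, alpha = config$alpha)
        } else {
            list(members = labs, excluded = character(),
                 values = vals[[1]], H = NULL,
                 reason = "single data-set (no merging possible)")
        }
        systemMerges[[s]] <- mg
        macroValues[[s]] <- mg$values
        ids <- do.call(rbind, lapply(mg$members, function(l) {
            v <- cholByDataset[[l]]
            v <- v[v$contacting, ]
            data.frame(dataset = l, common_id = v$common_id,
                       tmax_ns = v$tmax_ns, stringsAsFactors = FALSE)
        }))
        macroIds[[s]] <- ids
    }

    okSystems <- sysLabels[vapply(systemMerges,
                                  function(m) length(m$members) > 0, TRUE)]
    crossMerge <- if (length(okSystems) >= 2L) {
        leaveOneOutMerge(macroValues[okSystems], alpha = config$alpha)
    } else {
        list(members = okSystems, excluded = character(),
             values = macroValues[[okSystems]], H = NULL,
             reason = "single macro-sample")
    }
    pooledIds <- do.call(rbind, macroIds[crossMerge$members])
    pooled <- pooledIds$tmax_ns
    out <- findOutliers(pooled, ids = seq_len(length(pooled)),
                        quantileType = config$quantileType)
    outRows <- pooledIds[out$outliers$id, , drop = FALSE]
    outlierCommon <- sort(unique(outRows$common_id))

    mergedSummaries <- do.call(rbind, c(
        lapply(okSystems, function(s) {
            sm <- summarizeTmax(macroValues[[s]], label = s,
                                quantileType = config$quantileType)
            sm$aggregated_us <- sum(vapply(systemMerges[[s]]$members,
                function(l) datasetMeta[[l]]$lengthNs, 0)) / 1000
            sm
        }),
        list({
            sm <- summarizeTmax(pooled, label = "ALL",
                                quantileType = config$quantileType)
            sm$aggregated_us <- sum(vapply(unlist(lapply(
                crossMerge$members,
                function(s) systemMerges[[s]]$members)),
                function(l) datasetMeta[[l]]$lengthNs, 0)) / 1000
            sm
        })))

    ## ---- density maps and hotspots ------------------------------------
    hotspotsBySystem <- list()
    for (s in okSystems) {
        members <- systemMerges[[s]]$members
        gs <- gridsSpecies[[s]][["CHOL"]][members]
        gridsBySystem[[s]] <- mergeGrids(gs)
        hotspotsBySystem[[s]] <- extractHotspots(gridsBySystem[[s]],
                                                 contour = config$siteContour,
                                                 minVoxels = config$minVoxels,
                                                 connectivity = config$connectivity)
    }
    hotspotTable <- do.call(rbind, lapply(names(hotspotsBySystem),
        function(s) {
            hs <- hotspotsBySystem[[s]]
            if (!length(hs)) return(NULL)
            data.frame(system = s,
                       id = vapply(hs, function(h) h@id, 0L),
                       peak = vapply(hs, function(h) h@peak, 0),
                       centroid_x = vapply(hs, function(h) h@centroid[1], 0),
                       centroid_y = vapply(hs, function(h) h@centroid[2], 0),
                       centroid_z = vapply(hs, function(h) h@centroid[3], 0),
                       volume = vapply(hs, function(h) h@volume, 0))
        }))

    ## ---- site assembly -------------------------------------------------
    refIds <- residues(refTopo)
    refIds <- refIds[refIds$monomer == refMono, ]
    outlierRef <- refIds$residue_id[refIds$seq_pos %in% outlierCommon]
    match <- matchOutliersToHotspots(outlierRef, hotspotsBySystem,
                                     refTopo, referenceCoords,
                                     matchRadius = config$matchRadius,
                                     groupRadius = config$groupRadius,
                                     residueMask = refFacing)
    sites <- match$sites
    segMap <- NULL
    resDf <- residues(refTopo)
    if ("helix" %in% names(resDf)) {
        segMap <- stats::setNames(paste(resDf$monomer, resDf$helix),
                                  resDf$residue_id)
    }
    if (!is.null(segMap)) {
        pos <- stats::setNames(resDf$seq_pos, resDf$residue_id)
        sites <- lapply(sites, classifyTopology, segmentMap = segMap,
                        sequencePositions = pos,
                        window = config$linearWindow)
    }

    ## ---- residence events, binding modes ------------------------------
    resSystems <- if (is.null(config$residenceSystems)) okSystems
    else intersect(config$residenceSystems, okSystems)
    eventsBySite <- lapply(sites, function(s) list())
    names(eventsBySite) <- vapply(sites, function(s) s@name, "")
    modesBySite <- stats::setNames(vector("list", length(sites)),
                                   names(eventsBySite))
    if (length(sites)) {
        for (s in resSystems) {
            sys <- study[[s]]
            grid <- gridsBySystem[[s]]
            for (r in seq_along(sys$replicas)) {
                rep <- sys$replicas[[r]]
                topo <- rep$topology
                monos <- monomerLabels(topo)
                res <- residues(topo)
                for (mi in seq_along(monos)) {
                    m <- monos[mi]
                    label <- sprintf("%s.%d%s", s, r, letters[mi])
                    ft <- fittedCache[[label]]
                    cr <- contactsByDataset[[label]]
                    for (si in seq_along(sites)) {
                        site <- sites[[si]]
                        ## site residues mapped into this monomer
                        sitePos <- refIds$seq_pos[refIds$residue_id %in%
                                                  site@residueIds]
                        monoIds <- res$residue_id[res$monomer == m &
                                                  res$seq_pos %in% sitePos]
                        runs <- cr@runs
                        cand <- unique(runs$molecule_id[
                            runs$residue_id %in% monoIds &
                            runs$species == "CHOL"])
                        if (!length(cand))
                            next
                        evs <- list()
                        posesAcc <- list()
                        for (mol in cand) {
                            lb <- lipidBeads(topo, moleculeIds = mol)
                            lc <- ft@coords[, lb, , drop = FALSE]
                            pose <- referenceBoundPose(lc, site, grid)
                            if (is.null(pose))
                                next
                            rmsd <- poseRMSD(lc, pose$coords)
                            ev <- residenceEvents(rmsd,
                                                  boundCutoff = config$boundCutoff,
                                                  unboundCutoff = config$unboundCutoff,
                                                  dt = frameInterval(ft))
                            if (!nrow(ev))
                                next
                            ev$molecule_id <- mol
                            evs[[length(evs) + 1L]] <- ev
                            bf <- unlist(lapply(seq_len(nrow(ev)), function(e)
                                seq(ev$start_frame[e], ev$end_frame[e], by = 5L)))
                            if (length(bf))
                                posesAcc[[length(posesAcc) + 1L]] <-
                                    matrix(lc[bf, , ], nrow = length(bf))
                        }
                        if (length(evs)) {
                            evd <- do.call(rbind, evs)
                            evd$dataset <- label
                            nm <- site@name
                            eventsBySite[[nm]][[label]] <- evd
                            modesBySite[[nm]] <-
                                c(modesBySite[[nm]], posesAcc)
                        }
                    }
                }
            }
        }
    }
    siteSummaries <- NULL
    eventsDf <- NULL
    for (si in seq_along(sites)) {
        nm <- sites[[si]]@name
        sm <- summarizeSite(eventsBySite[[nm]],
                            thresholdSpecific = config$thresholdSpecific)
        sm$site <- nm
        poses <- modesBySite[[nm]]
        if (length(poses)) {
            pm <- do.call(rbind, poses)
            modes <- countBindingModes(pm, clusterRmsd = config$clusterRmsd)
            sites[[si]]@nBindingModes <- as.integer(modes$n_modes)
            sm$n_binding_modes <- modes$n_modes
            sm$modes_low_confidence <- modes$low_confidence
        } else {
            sm$n_binding_modes <- NA_integer_
            sm$modes_low_confidence <- NA
        }
        siteSummaries <- rbind(siteSummaries, sm)
        ev <- do.call(rbind, eventsBySite[[nm]])
        if (!is.null(ev) && nrow(ev)) {
            ev$site <- nm
            eventsDf <- rbind(eventsDf, ev)
        }
    }

    ## ---- selectivity ---------------------------------------------------
    selectivity <- NULL
    if (length(sites) && length(binSpecies) > 1L) {
        resLabs <- names(Filter(function(m) m$system %in% resSystems,
                                datasetMeta))
        prof <- speciesTmaxProfile(lapply(resLabs, function(l) {
            t <- tmaxAll[[l]]
            t$residue_id <- t$common_id
            t
        }))
        ## species grids cannot be merged across systems (different bulk
        ## densities), so selectivity uses the highest-priority residence
        ## system's merged grids
        selSys <- resSystems[length(resSystems)]
        sgrids <- lapply(stats::setNames(binSpecies, binSpecies),
            function(sp) mergeGrids(
                gridsSpecies[[selSys]][[sp]][systemMerges[[selSys]]$members]))
        for (si in seq_along(sites)) {
            site <- sites[[si]]
            siteCommon <- refIds$seq_pos[refIds$residue_id %in% site@residueIds]
            ## reuse the common-id profile restricted to this site
            siteForSel <- site
            siteForSel@residueIds <- as.integer(siteCommon)
            sel <- siteSelectivity(siteForSel, prof, sgrids)
            sel$perSpecies$site <- site@name
            sel$perSpecies$non_annular <- sel$non_annular
            selectivity <- rbind(selectivity, sel$perSpecies)
        }
    }

    ## ---- motifs --------------------------------------------------------
    motifs <- NULL
    if (!is.null(sequenceFasta))
        motifs <- scanMotifsFasta(sequenceFasta)

    manifest <- list(
        package = "cholmap",
        version = as.character(utils::packageVersion("cholmap")),
        config = unclass(config),
        seed = config$seed,
        conventions = list(
            quartiles = sprintf("linear interpolation (R type %d)",
                                config$quantileType),
            hotspot_connectivity = config$connectivity,
            pose_tie_break = "earliest frame",
            site_ranking = "matched outliers, then peak density"),
        systems = lapply(sysLabels, function(s) list(
            label = s,
            datasets = names(Filter(function(m) m$system == s, datasetMeta)))))

    report <- list(tmax = tmaxDf,
                   datasetSummaries = datasetSummaries,
                   merge = list(perSystem = systemMerges,
                                crossSystem = crossMerge,
                                mergedSummaries = mergedSummaries),
                   outliers = list(threshold_ns = out$threshold_ns,
                                   rows = outRows,
                                   common_ids = outlierCommon,
                                   reference_ids = outlierRef),
                   grids = gridsBySystem,
                   hotspots = list(bySystem = hotspotsBySystem,
                                   table = hotspotTable,
                                   nonReproducible = match$nonReproducible),
                   sites = sites,
                   siteSummaries = siteSummaries,
                   events = eventsDf,
                   selectivity = selectivity,
                   motifs = motifs,
                   manifest = manifest)
    if (!is.null(outDir))
        .writeReport(report, outDir, config)
    report
}

## CSV/JSON/DX emission; deterministic (no timestamps).
.writeReport <- function(report, outDir, config) {
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
        stop(sprintf("cannot create directory '%s'", outDir))
    wcsv <- function(df, name) {
        if (!is.null(df) && nrow(df))
            utils::write.csv(df, file.path(outDir, name), row.names = FALSE)
    }
    wcsv(report$tmax, "tmax.csv")
    wcsv(report$datasetSummaries, "dataset_summary.csv")
    wcsv(report$merge$mergedSummaries, "merged_summary.csv")
    wcsv(report$outliers$rows, "outliers.csv")
    wcsv(report$hotspots$table, "hotspots.csv")
    wcsv(report$siteSummaries, "site_summary.csv")
    wcsv(report$events, "events.csv")
    wcsv(report$selectivity, "selectivity.csv")
    wcsv(report$motifs, "motifs.csv")
    sitesJson <- lapply(report$sites, function(s) list(
        name = s@name, ranked = s@ranked,
        residues = s@residueIds, outliers = s@outlierIds,
        hotspots = s@hotspotIds, topology = s@topologyClass,
        n_binding_modes = s@nBindingModes, peak = s@peakDensity,
        centroid = s@centroid))
    jsonlite::write_json(sitesJson, file.path(outDir, "sites.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    tests <- list(perSystem = lapply(report$merge$perSystem, function(m)
        list(members = m$members, excluded = m$excluded,
             reason = m$reason, H = m$H)),
        crossSystem = list(members = report$merge$crossSystem$members,
                           excluded = report$merge$crossSystem$excluded,
                           reason = report$merge$crossSystem$reason,
                           H = report$merge$crossSystem$H),
        outlier_threshold_ns = report$outliers$threshold_ns)
    jsonlite::write_json(tests, file.path(outDir, "tests.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    if (isTRUE(config$writeGrids)) {
        for (s in names(report$grids))
            writeOpenDX(report$grids[[s]],
                        file.path(outDir, sprintf("sdf_%s.dx", s)))
    }
    invisible(outDir)
}
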