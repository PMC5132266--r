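#' Detect residue-lipid contacts along a trajectory
#'
#' A protein residue and a lipid molecule are in contact at a frame iff
#' any of their bead pairs is within `cutoff` (6 Angstrom by default,
#' the first minimum of the bead radial distribution function in
#' MARTINI-like models), using minimum-image distances under the
#' orthorhombic box unless `pbc = FALSE`.  Only residues in
#' `residueMask` are evaluated.  The default engine is a cell-list
#' neighbor search (cell edge >= cutoff); `method = "brute"` runs a
#' plain all-pairs scan in R and is kept as an independent check
#' (it expects in-box coordinates when `pbc = FALSE`).
#'
#' @param traj A [Trajectory-class].
#' @param topology A [BeadTopology-class].
#' @param cutoff Contact cutoff in Angstrom.
#' @param species Lipid species to include (default all present).
#' @param residueMask Residue ids to evaluate; defaults to the
#'   membrane-facing residues.
#' @param pbc Apply minimum-image convention (default TRUE).
#' @param method `"cell"` (default) or `"brute"`.
#' @return A [ContactRuns-class].
#' @export
detectContacts <- function(traj, topology, cutoff = 6,
                           species = NULL, residueMask = NULL,
                           pbc = TRUE, method = c("cell", "brute")) {
    method <- match.arg(method)
    if (cutoff <= 0)
        stop("cutoff must be positive")
    if (is.null(residueMask))
        residueMask <- membraneFacing(topology)
    residueMask <- sort(unique(residueMask))
    if (!length(residueMask))
        stop("empty residue mask")
    lip <- lipids(topology)
    if (is.null(species))
        species <- unique(lip$species)
    mols <- lip$molecule_id[lip$species %in% species]
    if (!length(mols))
        stop(sprintf("no lipids of species %s", paste(species, collapse = ",")))

    bd <- topology@beads
    rb <- bd[bd$owner == "residue" & bd$owner_id %in% residueMask, ]
    lb <- bd[bd$owner == "lipid" & bd$owner_id %in% mols, ]
    resOf <- match(rb$owner_id, residueMask)
    lipOf <- match(lb$owner_id, mols)

    if (method == "cell") {
        df <- contact_runs_cpp(traj@coords, as.integer(rb$index),
                               as.integer(resOf), as.integer(lb$index),
                               as.integer(lipOf), traj@box, cutoff, pbc)
    } else {
        df <- .bruteContactRuns(traj, rb$index, resOf, lb$index, lipOf,
                                cutoff, pbc)
    }
    molIds <- mols[df$lip]
    runs <- data.frame(residue_id = residueMask[df$res],
                       molecule_id = molIds,
                       species = lip$species[match(molIds, lip$molecule_id)],
                       start = df$start, end = df$end,
                       stringsAsFactors = FALSE)
    runs <- runs[order(runs$residue_id, runs$molecule_id, runs$start), ]
    rownames(runs) <- NULL
    new("ContactRuns", runs = runs, residueIds = as.integer(residueMask),
        nFrames = nFrames(traj), dt = frameInterval(traj), cutoff = cutoff)
}

## All-pairs reference engine: O(frames x residue beads x lipid beads).
.bruteContactRuns <- function(traj, resBead, resOf, lipBead, lipOf,
                              cutoff, pbc) {
    nf <- nFrames(traj)
    nRes <- max(resOf)
    nLip <- max(lipOf)
    inRun <- matrix(-1L, nRes, nLip)
    out <- list()
    cut2 <- cutoff^2
    for (f in seq_len(nf)) {
        fr <- beadCoords(traj, f)
        box <- boxLengths(traj, f)
        A <- fr[resBead, , drop = FALSE]
        B <- fr[lipBead, , drop = FALSE]
        hit <- matrix(FALSE, nRes, nLip)
        for (i in seq_len(nrow(A))) {
            d <- sweep(B, 2, A[i, ])
            if (pbc)
                d <- minImageDisplacement(d, box)
            ok <- rowSums(d * d) <= cut2
            if (any(ok))
                hit[resOf[i], unique(lipOf[ok])] <- TRUE
        }
        opening <- hit & inRun < 0
        closing <- !hit & inRun >= 0
        inRun[opening] <- f
        if (any(closing)) {
            idx <- which(closing, arr.ind = TRUE)
            out[[length(out) + 1L]] <-
                data.frame(res = idx[, 1], lip = idx[, 2],
                           start = inRun[closing], end = f - 1L)
            inRun[closing] <- -1L
        }
    }
    open <- inRun >= 0
    if (any(open)) {
        idx <- which(open, arr.ind = TRUE)
        out[[length(out) + 1L]] <- data.frame(res = idx[, 1], lip = idx[, 2],
                                              start = inRun[open], end = nf)
    }
    if (!length(out))
        return(data.frame(res = integer(), lip = integer(),
                          start = integer(), end = integer()))
    do.call(rbind, out)
}

#' Reconstruct the boolean occupancy series of one residue-lipid pair
#'
#' @param contacts A [ContactRuns-class].
#' @param residueId,moleculeId The pair to extract.
#' @return Logical vector of length `nFrames`.
#' @export
occupancySeries <- function(contacts, residueId, moleculeId) {
    ok <- contacts@runs$residue_id == residueId &
        contacts@runs$molecule_id == moleculeId
    v <- logical(contacts@nFrames)
    for (i in which(ok))
        v[contacts@runs$start[i]:contacts@runs$end[i]] <- TRUE
    v
}

#' Maximum occupancy times per residue and species
#'
#' The maximum occupancy time t_max of a residue is the longest time it
#' stays continuously in contact with one single lipid molecule; it
#' separates specific (microsecond) from random (nanosecond) contacts.
#' Runs of one (residue, molecule) pair separated by at most
#' `gapTolerance` non-contact frames are bridged before taking the
#' maximum (default 0: strict runs).
#'
#' @param contacts A [ContactRuns-class].
#' @param gapTolerance Interior non-contact frames allowed inside a run.
#' @param label Data-set label stored in the output.
#' @param species Species universe for the output; defaults to the
#'   species seen in `contacts` (pass explicitly to obtain zero rows for
#'   a species that never contacted).
#' @return A data.frame (`dataset`, `residue_id`, `species`, `tmax_ns`,
#'   `contacting`); masked residues without any contact of a species get
#'   `tmax_ns = 0`, `contacting = FALSE`.
#' @examples
#' ## series 1,1,1,0,1,1 at dt = 1 ns: t_max 3 ns strict, 6 ns with
#' ## gapTolerance 1
#' @export
computeTmax <- function(contacts, gapTolerance = 0L, label = "data",
                        species = NULL) {
    runs <- contacts@runs
    dt <- contacts@dt
    speciesAll <- if (is.null(species)) unique(runs$species) else species
    if (!length(speciesAll))
        speciesAll <- "CHOL"
    out <- list()
    for (sp in speciesAll) {
        r <- runs[runs$species == sp, ]
        tmax <- stats::setNames(numeric(length(contacts@residueIds)),
                                contacts@residueIds)
        if (nrow(r)) {
            key <- paste(r$residue_id, r$molecule_id)
            for (k in unique(key)) {
                rr <- r[key == k, ]
                len <- .maxRunLength(rr$start, rr$end, gapTolerance)
                rid <- as.character(rr$residue_id[1])
                tmax[rid] <- max(tmax[rid], len * dt)
            }
        }
        out[[sp]] <- data.frame(dataset = label,
                                residue_id = contacts@residueIds,
                                species = sp,
                                tmax_ns = unname(tmax),
                                contacting = unname(tmax) > 0,
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## longest merged run length in frames, bridging gaps <= gapTolerance
.maxRunLength <- function(start, end, gapTolerance) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    best <- 0L
    curS <- start[1]; curE <- end[1]
    for (i in seq_along(start)[-1]) {
        if (start[i] - curE - 1L <= gapTolerance) {
            curE <- max(curE, end[i])
        } else {
            best <- max(best, curE - curS + 1L)
            curS <- start[i]; curE <- end[i]
        }
    }
    max(best, curE - curS + 1L)
}

#' Average per-residue t_max profiles across data-sets
#'
#' Arithmetic mean of per-residue maximum occupancy times across
#' data-sets, per species; supports point queries for named residues
#' (e.g. residues known to coordinate other lipids).  A residue missing
#' from one data-set is treated as t_max = 0 there, with a note.
#'
#' @param tables A list of data.frames from [computeTmax()], or one
#'   data.frame with a `dataset` column.
#' @param residueIds Optional residue universe; defaults to the union.
#' @return data.frame (`residue_id`, `species`, `mean_tmax_ns`,
#'   `contacted`): `contacted` is FALSE when no data-set ever saw a
#'   contact.
#' @export
speciesTmaxProfile <- function(tables, residueIds = NULL) {
    if (is.data.frame(tables))
        tables <- split(tables, tables$dataset)
    allRes <- if (is.null(residueIds))
        sort(unique(unlist(lapply(tables, function(t) t$residue_id))))
    else sort(unique(residueIds))
    allSp <- sort(unique(unlist(lapply(tables, function(t) t$species))))
    out <- expand.grid(residue_id = allRes, species = allSp,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    acc <- matrix(0, nrow(out), length(tables))
    noted <- FALSE
    for (j in seq_along(tables)) {
        t <- tables[[j]]
        i <- match(paste(out$residue_id, out$species),
                   paste(t$residue_id, t$species))
        if (anyNA(i) && !noted) {
            message("some residues are absent from a data-set; treated as t_max = 0")
            noted <- TRUE
        }
        acc[, j] <- ifelse(is.na(i), 0, t$tmax_ns[i])
    }
    out$mean_tmax_ns <- rowMeans(acc)
    out$contacted <- rowSums(acc > 0) > 0
    out
}
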