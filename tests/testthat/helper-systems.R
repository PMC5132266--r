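## In-code fixtures: tiny topologies and trajectories built directly.

## A topology of nRes single-residue groups and nLip single-species
## lipids, with configurable beads per unit.
makeToyTopology <- function(nRes = 2L, beadsPerRes = 1L, nLip = 3L,
                            beadsPerLip = 1L, species = "CHOL",
                            monomer = "A") {
    species <- rep_len(species, nLip)
    res <- data.frame(residue_id = seq_len(nRes),
                      name = rep("ALA", nRes),
                      monomer = rep_len(monomer, nRes),
                      membrane_facing = TRUE,
                      resid_orig = seq_len(nRes),
                      stringsAsFactors = FALSE)
    res$seq_pos <- stats::ave(res$residue_id, res$monomer, FUN = seq_along)
    lip <- data.frame(molecule_id = seq_len(nLip), species = species,
                      name = ifelse(species == "CHOL", "CHOL",
                             ifelse(species == "PC", "DSPC", "POPE")),
                      stringsAsFactors = FALSE)
    beads <- data.frame(
        index = seq_len(nRes * beadsPerRes + nLip * beadsPerLip),
        owner = c(rep("residue", nRes * beadsPerRes),
                  rep("lipid", nLip * beadsPerLip)),
        owner_id = c(rep(seq_len(nRes), each = beadsPerRes),
                     rep(seq_len(nLip), each = beadsPerLip)),
        name = "BB", stringsAsFactors = FALSE)
    new("BeadTopology", residues = res, lipids = lip, beads = beads,
        nBeads = nrow(beads))
}

## Trajectory from an explicit frames x beads x 3 array (or a single
## frame matrix, repeated).
makeToyTrajectory <- function(coords, box = c(50, 50, 50), dt = 1) {
    if (length(dim(coords)) == 2L) {
        coords <- array(rep(coords, each = 1),
                        dim = c(1L, nrow(coords), 3L))
    }
    nf <- dim(coords)[1]
    new("Trajectory", coords = coords, dt = dt,
        box = matrix(box, nf, 3, byrow = TRUE),
        times = (seq_len(nf) - 1) * dt)
}

## Random toy system for engine-vs-oracle comparisons.
randomToySystem <- function(seed, nRes = 4L, nLip = 6L, nFrames = 20L,
                            box = c(30, 30, 30), beadsPerRes = 2L,
                            beadsPerLip = 2L) {
    set.seed(seed)
    topo <- makeToyTopology(nRes, beadsPerRes, nLip, beadsPerLip)
    nb <- nBeads(topo)
    coords <- array(stats::runif(nFrames * nb * 3, 0, box[1]),
                    dim = c(nFrames, nb, 3))
    list(topology = topo, trajectory = makeToyTrajectory(coords, box))
}

## ContactRuns built from a dense logical series for one pair.
runsFromSeries <- function(series, dt = 1, residue = 1L, molecule = 1L,
                           species = "CHOL") {
    r <- rle(series)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    runs <- data.frame(residue_id = residue, molecule_id = molecule,
                       species = species,
                       start = starts[keep], end = ends[keep],
                       stringsAsFactors = FALSE)
    new("ContactRuns", runs = runs, residueIds = residue,
        nFrames = length(series), dt = dt, cutoff = 6)
}

## Exhaustive triple-loop motif enumerator, independent of scanMotifs.
oracleScan <- function(seq, kind, lo = 1, hi = 5) {
    aa <- strsplit(seq, "")[[1]]
    first <- if (kind == "CRAC") c("V", "L") else c("R", "K")
    last <- if (kind == "CRAC") c("R", "K") else c("V", "L")
    out <- NULL
    n <- length(aa)
    for (i in seq_len(n)) if (aa[i] %in% first)
        for (j in seq_len(n)) if (j > i && aa[j] %in% c("Y", "F") &&
                                  (j - i - 1) >= lo && (j - i - 1) <= hi)
            for (k in seq_len(n)) if (k > j && aa[k] %in% last &&
                                      (k - j - 1) >= lo && (k - j - 1) <= hi)
                out <- rbind(out, c(i, j, k))
    out
}
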