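#' @import methods
NULL

## Central S4 containers.  Coordinates are always stored in Angstrom and
## times in nanoseconds; GRO input (nm) is converted on read.

#' Bead-level topology of a protein/membrane system
#'
#' Describes which beads belong to which protein residue or lipid
#' molecule.  Bead ownership is stored as a single table (one row per
#' bead), which makes the residue/lipid bead index sets disjoint by
#' construction.
#'
#' @slot residues data.frame with columns `residue_id` (integer), `name`
#'   (3-letter code), `monomer` (character label partitioning the protein
#'   into monomers), `membrane_facing` (logical mask of residues exposed
#'   to the bilayer).
#' @slot lipids data.frame with columns `molecule_id` (integer) and
#'   `species` (one of `"CHOL"`, `"PC"`, `"PE"`, `"OTHER"`).
#' @slot beads data.frame with one row per bead: `index` (1-based bead
#'   index), `owner` (`"residue"` or `"lipid"`), `owner_id` (the owning
#'   residue or molecule id), `name` (bead name).
#' @slot nBeads integer, total number of beads.
#'
#' @seealso [readTopology()], [residueBeads()], [lipidBeads()]
#' @export
setClass("BeadTopology",
    slots = c(
        residues = "data.frame",
        lipids   = "data.frame",
        beads    = "data.frame",
        nBeads   = "integer"
    )
)

setValidity("BeadTopology", function(object) {
    msg <- character()
    res <- object@residues
    lip <- object@lipids
    bd <- object@beads
    need <- c("residue_id", "name", "monomer", "membrane_facing")
    if (!all(need %in% names(res)))
        msg <- c(msg, "residues must have residue_id, name, monomer, membrane_facing")
    if (!all(c("molecule_id", "species") %in% names(lip)))
        msg <- c(msg, "lipids must have molecule_id, species")
    if (!all(c("index", "owner", "owner_id") %in% names(bd)))
        msg <- c(msg, "beads must have index, owner, owner_id")
    if (length(msg))
        return(msg)
    if (anyDuplicated(res$residue_id))
        msg <- c(msg, "duplicated residue_id")
    if (anyDuplicated(lip$molecule_id))
        msg <- c(msg, "duplicated lipid molecule_id")
    if (anyDuplicated(bd$index))
        msg <- c(msg, "a bead is assigned more than once")
    if (!all(bd$owner %in% c("residue", "lipid")))
        msg <- c(msg, "bead owner must be 'residue' or 'lipid'")
    rid <- bd$owner_id[bd$owner == "residue"]
    lid <- bd$owner_id[bd$owner == "lipid"]
    if (!all(rid %in% res$residue_id))
        msg <- c(msg, "bead assigned to unknown residue")
    if (!all(lid %in% lip$molecule_id))
        msg <- c(msg, "bead assigned to unknown lipid")
    if (nrow(lip) && !all(lip$molecule_id %in% lid))
        msg <- c(msg, "every lipid must own at least one bead")
    if (!all(lip$species %in% c("CHOL", "PC", "PE", "OTHER")))
        msg <- c(msg, "lipid species must be CHOL, PC, PE or OTHER")
    if (object@nBeads != nrow(bd))
        msg <- c(msg, "nBeads does not match the bead table")
    if (length(msg)) msg else TRUE
})

#' Coarse-grained coordinate trajectory
#'
#' @slot coords numeric array, frames x beads x 3, in Angstrom.
#' @slot dt numeric, frame interval in nanoseconds.
#' @slot box numeric matrix, frames x 3 orthorhombic box lengths in
#'   Angstrom.
#' @slot times numeric vector of frame times in nanoseconds.
#'
#' @seealso [readTrajectory()], [nFrames()], [beadCoords()]
#' @export
setClass("Trajectory",
    slots = c(
        coords = "array",
        dt     = "numeric",
        box    = "matrix",
        times  = "numeric"
    )
)

setValidity("Trajectory", function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
        msg <- c(msg, "coords must be a frames x beads x 3 array")
    if (!all(is.finite(object@coords)))
        msg <- c(msg, "coords contain non-finite values")
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
        msg <- c(msg, "dt must be a single positive number (ns)")
    if (length(d) == 3L) {
        if (nrow(object@box) != d[1] || ncol(object@box) != 3L)
            msg <- c(msg, "box must be a frames x 3 matrix")
        if (length(object@times) != d[1])
            msg <- c(msg, "times must have one entry per frame")
    }
    if (!all(is.finite(object@box)) || any(object@box <= 0))
        msg <- c(msg, "box lengths must be positive and finite")
    if (length(msg)) msg else TRUE
})

#' Rigid-body least-squares superposition
#'
#' Result of a Kabsch fit of one frame onto a reference over a bead
#' selection.
#'
#' @slot rotation 3 x 3 proper rotation matrix (determinant +1).
#' @slot translation length-3 numeric vector in Angstrom.
#' @slot rmsdBefore RMSD over the selection before fitting (Angstrom).
#' @slot rmsdAfter RMSD over the selection after fitting (Angstrom).
#'
#' @seealso [fitFrame()]
#' @export
setClass("Superposition",
    slots = c(
        rotation    = "matrix",
        translation = "numeric",
        rmsdBefore  = "numeric",
        rmsdAfter   = "numeric"
    )
)

setValidity("Superposition", function(object) {
    msg <- character()
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
        msg <- c(msg, "rotation must be 3 x 3")
    else {
        if (abs(det(R) - 1) > 1e-6)
            msg <- c(msg, "rotation must be proper (det = +1)")
        if (max(abs(crossprod(R) - diag(3))) > 1e-6)
            msg <- c(msg, "rotation must be orthonormal")
    }
    if (length(object@translation) != 3L)
        msg <- c(msg, "translation must have length 3")
    if (object@rmsdAfter < 0)
        msg <- c(msg, "rmsdAfter must be >= 0")
    if (object@rmsdAfter > object@rmsdBefore + 1e-9)
        msg <- c(msg, "rmsdAfter cannot exceed rmsdBefore")
    if (length(msg)) msg else TRUE
})

#' Voxelized spatial density of lipid beads
#'
#' Per-voxel hit counts of lipid beads accumulated over fitted frames,
#' with the normalization metadata needed to express the density as a
#' spatial density probability function whose bulk average is one.
#'
#' @slot origin length-3 numeric, position of the corner of voxel
#'   (1,1,1), in Angstrom.
#' @slot edge numeric, voxel edge length in Angstrom (default 1, i.e.
#'   1 cubic Angstrom voxels).
#' @slot counts 3-D integer array of bead-frame observations.
#' @slot nFrames integer, number of frames binned.
#' @slot refDensity numeric, reference (bulk) bead density in beads per
#'   cubic Angstrom.
#' @slot nOutside integer, bead-frame observations falling outside the
#'   grid (tallied, not binned).
#' @slot species character, the lipid species binned.
#'
#' @seealso [computeSDF()], [mergeGrids()], [extractHotspots()]
#' @export
setClass("DensityGrid",
    slots = c(
        origin     = "numeric",
        edge       = "numeric",
        counts     = "array",
        nFrames    = "integer",
        refDensity = "numeric",
        nOutside   = "integer",
        species    = "character"
    )
)

setValidity("DensityGrid", function(object) {
    msg <- character()
    if (length(object@origin) != 3L)
        msg <- c(msg, "origin must have length 3")
    if (length(object@edge) != 1L || object@edge <= 0)
        msg <- c(msg, "edge must be a single positive number")
    if (length(dim(object@counts)) != 3L)
        msg <- c(msg, "counts must be a 3-D array")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (object@nFrames < 0L)
        msg <- c(msg, "nFrames must be >= 0")
    if (object@refDensity <= 0)
        msg <- c(msg, "refDensity must be positive")
    if (length(msg)) msg else TRUE
})

#' Contact occupancy runs between residues and lipid molecules
#'
#' Sparse representation of per-residue, per-lipid-molecule boolean
#' contact series: only maximal runs of consecutive contact frames are
#' stored.  [occupancySeries()] reconstructs the dense boolean vector
#' for one (residue, molecule) pair.
#'
#' @slot runs data.frame with columns `residue_id`, `molecule_id`,
#'   `species`, `start`, `end` (1-based frame indices, inclusive).
#' @slot residueIds integer vector of all residues that were evaluated
#'   (the membrane-facing mask); residues absent from `runs` have no
#'   contact.
#' @slot nFrames integer, trajectory frame count.
#' @slot dt numeric, frame interval in ns.
#' @slot cutoff numeric, contact cutoff in Angstrom.
#'
#' @seealso [detectContacts()], [computeTmax()]
#' @export
setClass("ContactRuns",
    slots = c(
        runs       = "data.frame",
        residueIds = "integer",
        nFrames    = "integer",
        dt         = "numeric",
        cutoff     = "numeric"
    )
)

setValidity("ContactRuns", function(object) {
    msg <- character()
    need <- c("residue_id", "molecule_id", "species", "start", "end")
    if (!all(need %in% names(object@runs)))
        msg <- c(msg, "runs must have residue_id, molecule_id, species, start, end")
    else if (nrow(object@runs)) {
        if (any(object@runs$start < 1L) || any(object@runs$end > object@nFrames))
            msg <- c(msg, "run frames out of range")
        if (any(object@runs$end < object@runs$start))
            msg <- c(msg, "run end before start")
    }
    if (object@dt <= 0)
        msg <- c(msg, "dt must be positive")
    if (length(msg)) msg else TRUE
})

#' Connected high-density region of a density grid
#'
#' @slot id integer hotspot identifier (1 = highest peak).
#' @slot voxels integer matrix (n x 3) of voxel indices.
#' @slot centers numeric matrix (n x 3) of voxel center coordinates in
#'   Angstrom.
#' @slot peak numeric, maximum per-voxel hit count in the hotspot.
#' @slot centroid length-3 numeric, count-weighted centroid in Angstrom.
#' @slot volume numeric, hotspot volume in cubic Angstrom.
#'
#' @seealso [extractHotspots()]
#' @export
setClass("Hotspot",
    slots = c(
        id       = "integer",
        voxels   = "matrix",
        centers  = "matrix",
        peak     = "numeric",
        centroid = "numeric",
        volume   = "numeric"
    )
)

#' A ranked lipid interaction site
#'
#' A site assembles statistically anomalous residues (maximum occupancy
#' time outliers) with a reproducible spatial density hotspot.
#' Density-only candidates (reproducible hotspot, no overlapping
#' outlier) carry `ranked = FALSE`.
#'
#' @slot name character site label.
#' @slot residueIds integer, all residues belonging to the site.
#' @slot outlierIds integer, the subset that are t_max outliers.
#' @slot hotspotIds character, identifiers of member hotspots
#'   (`"<system>:<id>"`).
#' @slot topologyClass `"linear"`, `"non-linear"` or `NA` before
#'   classification.
#' @slot nBindingModes integer, number of distinct bound orientations
#'   (NA before residence analysis).
#' @slot peakDensity numeric, highest member-hotspot peak (hits per
#'   voxel).
#' @slot centroid length-3 numeric, site centroid in Angstrom.
#' @slot voxelCenters numeric matrix of member super-contour voxel
#'   centers in Angstrom.
#' @slot ranked logical, whether the site has outlier support.
#'
#' @seealso [matchOutliersToHotspots()], [classifyTopology()]
#' @export
setClass("InteractionSite",
    slots = c(
        name          = "character",
        residueIds    = "integer",
        outlierIds    = "integer",
        hotspotIds    = "character",
        topologyClass = "character",
        nBindingModes = "integer",
        peakDensity   = "numeric",
        centroid      = "numeric",
        voxelCenters  = "matrix",
        ranked        = "logical"
    )
)

setValidity("InteractionSite", function(object) {
    msg <- character()
    if (!all(object@outlierIds %in% object@residueIds))
        msg <- c(msg, "outlierIds must be a subset of residueIds")
    if (!object@topologyClass %in% c("linear", "non-linear", NA_character_))
        msg <- c(msg, "topologyClass must be 'linear' or 'non-linear'")
    if (length(msg)) msg else TRUE
})
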