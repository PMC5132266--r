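#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname nFrames
#' @export
setMethod("nFrames", "DensityGrid", function(x) x@nFrames)

#' @rdname nBeads
#' @export
setMethod("nBeads", "BeadTopology", function(x) x@nBeads)

#' @rdname nBeads
#' @export
setMethod("nBeads", "Trajectory", function(x) dim(x@coords)[2])

#' @rdname beadCoords
#' @export
setMethod("beadCoords", "Trajectory", function(x, frame = NULL) {
    if (is.null(frame))
        return(x@coords)
    m <- x@coords[frame, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    m
})

#' @rdname boxLengths
#' @export
setMethod("boxLengths", "Trajectory", function(x, frame = NULL) {
    if (is.null(frame)) x@box else x@box[frame, ]
})

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@dt)

#' @rdname residues
#' @export
setMethod("residues", "BeadTopology", function(x) x@residues)

#' @rdname lipids
#' @export
setMethod("lipids", "BeadTopology", function(x) x@lipids)

#' @rdname voxelCounts
#' @export
setMethod("voxelCounts", "DensityGrid", function(x) x@counts)

#' @rdname densityValues
#' @export
setMethod("densityValues", "DensityGrid", function(x) {
    denom <- x@refDensity * x@edge^3 * max(x@nFrames, 1L)
    x@counts / denom
})

#' Bead indices of protein residues
#'
#' @param topology A [BeadTopology-class].
#' @param residueIds Residue ids; default all protein residues.
#' @return Sorted integer vector of bead indices.
#' @export
residueBeads <- function(topology, residueIds = NULL) {
    bd <- topology@beads
    keep <- bd$owner == "residue"
    if (!is.null(residueIds))
        keep <- keep & bd$owner_id %in% residueIds
    sort(bd$index[keep])
}

#' Bead indices of lipid molecules
#'
#' @param topology A [BeadTopology-class].
#' @param moleculeIds Lipid molecule ids; default all lipids.
#' @param species Optional species filter applied before `moleculeIds`.
#' @return Sorted integer vector of bead indices.
#' @export
lipidBeads <- function(topology, moleculeIds = NULL, species = NULL) {
    lip <- topology@lipids
    if (!is.null(species))
        moleculeIds0 <- lip$molecule_id[lip$species %in% species]
    else
        moleculeIds0 <- lip$molecule_id
    if (!is.null(moleculeIds))
        moleculeIds0 <- intersect(moleculeIds0, moleculeIds)
    bd <- topology@beads
    sort(bd$index[bd$owner == "lipid" & bd$owner_id %in% moleculeIds0])
}

#' Residue ids flagged as membrane facing
#'
#' @param topology A [BeadTopology-class].
#' @return Integer vector of residue ids.
#' @export
membraneFacing <- function(topology) {
    res <- topology@residues
    res$residue_id[res$membrane_facing]
}

#' Monomer labels present in a topology
#'
#' @param topology A [BeadTopology-class].
#' @return Character vector of unique monomer labels.
#' @export
monomerLabels <- function(topology) unique(topology@residues$monomer)

#' Residue ids belonging to one monomer
#'
#' @param topology A [BeadTopology-class].
#' @param monomer A monomer label.
#' @return Integer vector of residue ids.
#' @export
monomerResidues <- function(topology, monomer) {
    res <- topology@residues
    res$residue_id[res$monomer == monomer]
}

setMethod("show", "BeadTopology", function(object) {
    cat("BeadTopology:", nrow(object@residues), "residues (",
        length(monomerLabels(object)), "monomer(s) ),",
        nrow(object@lipids), "lipids,", object@nBeads, "beads\n")
    if (nrow(object@lipids)) {
        tab <- table(object@lipids$species)
        cat("  lipid species:",
            paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
    }
    cat("  membrane-facing residues:",
        sum(object@residues$membrane_facing), "\n")
})

setMethod("show", "Trajectory", function(object) {
    d <- dim(object@coords)
    cat("Trajectory:", d[1], "frames x", d[2], "beads; dt =",
        object@dt, "ns; span =", d[1] * object@dt, "ns\n")
    cat("  box (frame 1):",
        paste(sprintf("%.1f", object@box[1, ]), collapse = " x "), "A\n")
})

setMethod("show", "Superposition", function(object) {
    cat(sprintf("Superposition: RMSD %.4f -> %.4f A\n",
                object@rmsdBefore, object@rmsdAfter))
})

setMethod("show", "DensityGrid", function(object) {
    d <- dim(object@counts)
    cat("DensityGrid [", object@species, "]: ",
        paste(d, collapse = " x "), " voxels (edge ",
        object@edge, " A), ", object@nFrames, " frames\n", sep = "")
    cat(sprintf("  ref density %.3g beads/A^3; hits in grid %d; outside %d\n",
                object@refDensity, sum(object@counts), object@nOutside))
})

setMethod("show", "ContactRuns", function(object) {
    cat("ContactRuns:", nrow(object@runs), "runs over",
        length(object@residueIds), "residues,", object@nFrames,
        "frames (cutoff", object@cutoff, "A)\n")
})

setMethod("show", "Hotspot", function(object) {
    cat(sprintf("Hotspot %d: peak %.0f hits, %d voxels (%.0f A^3), centroid (%.1f, %.1f, %.1f)\n",
                object@id, object@peak, nrow(object@voxels), object@volume,
                object@centroid[1], object@centroid[2], object@centroid[3]))
})

setMethod("show", "InteractionSite", function(object) {
    cat(sprintf("InteractionSite %s [%s%s]: %d residues, %d outliers, peak %.0f\n",
                object@name,
                ifelse(is.na(object@topologyClass), "unclassified",
                       object@topologyClass),
                if (object@ranked) "" else ", density-only candidate",
                length(object@residueIds), length(object@outlierIds),
                object@peakDensity))
})
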