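#' @include AllClasses.R
NULL

#' Number of frames in a trajectory-like object
#'
#' @param x An object with a time dimension (a [Trajectory-class] or a
#'   [DensityGrid-class]).
#' @return An integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of beads described by an object
#'
#' @param x A [BeadTopology-class] or [Trajectory-class].
#' @return An integer scalar.
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' Bead coordinates
#'
#' @param x A [Trajectory-class].
#' @param frame Optional frame index; when given, a beads x 3 matrix is
#'   returned instead of the full frames x beads x 3 array.
#' @return A numeric array (or matrix) of coordinates in Angstrom.
#' @export
setGeneric("beadCoords", function(x, frame = NULL) standardGeneric("beadCoords"))

#' Per-frame orthorhombic box lengths
#'
#' @param x A [Trajectory-class].
#' @param frame Optional frame index.
#' @return A frames x 3 matrix (or length-3 vector) of box lengths in
#'   Angstrom.
#' @export
setGeneric("boxLengths", function(x, frame = NULL) standardGeneric("boxLengths"))

#' Frame interval
#'
#' @param x A [Trajectory-class].
#' @return The frame spacing in nanoseconds.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Protein residue table
#'
#' @param x A [BeadTopology-class].
#' @return A data.frame with columns `residue_id`, `name`, `monomer`,
#'   `membrane_facing`.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' Lipid molecule table
#'
#' @param x A [BeadTopology-class].
#' @return A data.frame with columns `molecule_id`, `species`.
#' @export
setGeneric("lipids", function(x) standardGeneric("lipids"))

#' Raw per-voxel hit counts of a density grid
#'
#' @param x A [DensityGrid-class].
#' @return A 3-D integer array of bead-frame observations per voxel.
#' @export
setGeneric("voxelCounts", function(x) standardGeneric("voxelCounts"))

#' Normalized spatial density probability function
#'
#' Per-voxel density normalized by the reference (bulk) density, the
#' voxel volume and the number of frames, so that the bulk average is 1.
#'
#' @param x A [DensityGrid-class].
#' @return A 3-D numeric array, same shape as `voxelCounts(x)`.
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
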