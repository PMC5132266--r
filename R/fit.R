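#' Least-squares superposition of a frame onto a reference (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `frame[selection, ]` and `reference[selection, ]`, then applies the
#' transformation to all beads of the frame.  A reflection guard
#' enforces a proper rotation (determinant +1).
#'
#' @param frame Beads x 3 coordinate matrix (Angstrom).
#' @param reference Beads x 3 coordinate matrix with the same bead
#'   indexing.
#' @param selection Integer vector of bead indices used for the fit
#'   (at least 3 non-collinear beads).
#' @param refSelection Bead indices of the corresponding atoms in the
#'   reference (default `selection`); lets one monomer be superposed
#'   onto another with parallel bead ordering.
#' @return A list with elements `superposition` (a
#'   [Superposition-class]) and `coords` (the transformed frame).
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' fit <- fitFrame(ref, ref, seq_len(10))
#' fit$superposition@rmsdAfter  # 0
#' @export
fitFrame <- function(frame, reference, selection, refSelection = selection) {
    if (length(selection) < 3L)
        stop("ill-conditioned fit: selection must contain at least 3 beads")
    A <- frame[selection, , drop = FALSE]
    B <- reference[refSelection, , drop = FALSE]
    if (nrow(A) != nrow(B))
        stop("selection must be present in both frames")
    ca <- colMeans(A)
    cb <- colMeans(B)
    A0 <- sweep(A, 2, ca)
    B0 <- sweep(B, 2, cb)
    ## collinear selections leave the rotation about the common axis
    ## undetermined
    if (qr(A0)$rank < 2L)
        stop("ill-conditioned fit: selection is collinear")
    H <- crossprod(A0, B0)
    sv <- svd(H)
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    rmsd0 <- sqrt(mean(rowSums((A - B)^2)))
    fitSel <- tcrossprod(A0, R)
    rmsd1 <- sqrt(mean(rowSums((fitSel - B0)^2)))
    trans <- cb - as.numeric(R %*% ca)
    sup <- new("Superposition", rotation = R, translation = trans,
               rmsdBefore = rmsd0, rmsdAfter = min(rmsd0, rmsd1))
    coords <- tcrossprod(frame, R)
    coords <- sweep(coords, 2, trans, "+")
    list(superposition = sup, coords = coords)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param traj A [Trajectory-class].
#' @param reference Beads x 3 reference coordinates; default the first
#'   frame of `traj`.
#' @param selection Bead indices defining the fit group.
#' @param refSelection Corresponding bead indices in the reference
#'   (default `selection`).
#' @return A list with `trajectory` (fitted [Trajectory-class]) and
#'   `rmsd` (per-frame RMSD after fitting, Angstrom).
#' @export
fitTrajectory <- function(traj, reference = NULL, selection,
                          refSelection = selection) {
    if (is.null(reference))
        reference <- beadCoords(traj, 1L)
    co <- traj@coords
    nf <- dim(co)[1]
    rmsd <- numeric(nf)
    for (i in seq_len(nf)) {
        fr <- co[i, , ]
        ft <- fitFrame(fr, reference, selection, refSelection)
        co[i, , ] <- ft$coords
        rmsd[i] <- ft$superposition@rmsdAfter
    }
    out <- traj
    out@coords <- co
    list(trajectory = out, rmsd = rmsd)
}
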