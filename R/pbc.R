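#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' @param a,b Numeric length-3 vectors, or n x 3 matrices of positions in
#'   Angstrom (recycled row-wise against each other).
#' @param box Length-3 vector of box lengths in Angstrom.
#' @return Numeric vector of minimum-image Euclidean distances.
#' @examples
#' minImageDistance(c(1, 0, 0), c(99, 0, 0), c(100, 100, 100))  # 2
#' @export
minImageDistance <- function(a, b, box) {
    stopifnot(all(box > 0))
    a <- matrix(a, ncol = 3)
    b <- matrix(b, ncol = 3)
    d <- a[rep_len(seq_len(nrow(a)), max(nrow(a), nrow(b))), , drop = FALSE] -
        b[rep_len(seq_len(nrow(b)), max(nrow(a), nrow(b))), , drop = FALSE]
    d <- minImageDisplacement(d, box)
    sqrt(rowSums(d * d))
}

#' Wrap displacement vectors into the minimum image
#'
#' @param d An n x 3 matrix of displacement vectors in Angstrom.
#' @param box Length-3 vector of box lengths in Angstrom.
#' @return An n x 3 matrix of wrapped displacements, each component in
#'   `[-box/2, box/2]`.
#' @export
minImageDisplacement <- function(d, box) {
    d <- matrix(d, ncol = 3)
    for (k in 1:3)
        d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
}

## Minimum over all cross pairs of minimum-image distances between two
## coordinate sets (one frame).  Used by contact brute force and the
## minimum-distance time series.
.minCrossDistance <- function(xa, xb, box, pbc = TRUE) {
    xa <- matrix(xa, ncol = 3)
    xb <- matrix(xb, ncol = 3)
    best <- Inf
    for (i in seq_len(nrow(xa))) {
        d <- sweep(xb, 2, xa[i, ])
        if (pbc)
            d <- minImageDisplacement(d, box)
        best <- min(best, min(rowSums(d * d)))
    }
    sqrt(best)
}
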