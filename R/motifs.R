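## CRAC/CARC cholesterol-recognition motif scanning.
##
## CRAC, read N- to C-terminal: apolar (V/L), 1-5 spacer residues,
## aromatic (Y/F), 1-5 spacer residues, basic (R/K).  CARC keeps the
## reading direction but lists the anchors in reverse order (basic,
## aromatic, apolar).  Spacers are counted as the residues strictly
## between consecutive anchors, so K490-Y495-V501 has spacers 4 and 5.
## Tryptophan does not qualify as the aromatic anchor.

.MOTIF_CLASSES <- list(apolar = c("V", "L"),
                       aromatic = c("Y", "F"),
                       basic = c("R", "K"))

#' Scan a protein sequence for CRAC/CARC motifs
#'
#' Enumerates all motif occurrences (overlaps allowed) with spacer
#' lengths in `spacerRange`, reporting anchor positions in the supplied
#' residue numbering.
#'
#' @param sequence One-letter amino-acid string (20-letter alphabet).
#' @param kinds Subset of `c("CRAC", "CARC")`.
#' @param spacerRange Length-2 integer vector, allowed number of
#'   residues strictly between consecutive anchors (default `c(1, 5)`).
#' @param offset Residue number of the first sequence position
#'   (default 1).
#' @return data.frame with `kind`, `apolar_pos`, `apolar`,
#'   `aromatic_pos`, `aromatic`, `basic_pos`, `basic`, `first`, `last`,
#'   `motif` (e.g. `"K490-Y495-V501"`, anchors listed N to C).
#' @examples
#' scanMotifs("KAAAAYAAAAAV", kinds = "CARC", offset = 490)
#' @export
scanMotifs <- function(sequence, kinds = c("CRAC", "CARC"),
                       spacerRange = c(1L, 5L), offset = 1L) {
    kinds <- match.arg(kinds, c("CRAC", "CARC"), several.ok = TRUE)
    stopifnot(length(spacerRange) == 2L, spacerRange[1] >= 0,
              spacerRange[2] >= spacerRange[1], offset >= 1)
    aa <- strsplit(toupper(sequence), "")[[1]]
    bad <- which(!aa %in% unname(.AA3TO1))
    if (length(bad))
        stop(sprintf("illegal character '%s' at position %d",
                     aa[bad[1]], bad[1] + offset - 1L))
    n <- length(aa)
    hits <- list()
    scan1 <- function(kind, first, mid, last) {
        p1 <- which(aa %in% first)
        p2 <- which(aa %in% mid)
        p3 <- which(aa %in% last)
        for (i in p1) {
            for (j in p2[p2 > i]) {
                s1 <- j - i - 1L
                if (s1 < spacerRange[1] || s1 > spacerRange[2])
                    next
                for (k in p3[p3 > j]) {
                    s2 <- k - j - 1L
                    if (s2 < spacerRange[1] || s2 > spacerRange[2])
                        next
                    hits[[length(hits) + 1L]] <<-
                        data.frame(kind = kind,
                                   i = i, j = j, k = k,
                                   stringsAsFactors = FALSE)
                }
            }
        }
    }
    if ("CRAC" %in% kinds)
        scan1("CRAC", .MOTIF_CLASSES$apolar, .MOTIF_CLASSES$aromatic,
              .MOTIF_CLASSES$basic)
    if ("CARC" %in% kinds)
        scan1("CARC", .MOTIF_CLASSES$basic, .MOTIF_CLASSES$aromatic,
              .MOTIF_CLASSES$apolar)
    if (!length(hits))
        return(.emptyMotifHits())
    h <- do.call(rbind, hits)
    num <- function(p) p + offset - 1L
    isCrac <- h$kind == "CRAC"
    out <- data.frame(kind = h$kind,
                      apolar_pos = ifelse(isCrac, num(h$i), num(h$k)),
                      apolar = ifelse(isCrac, aa[h$i], aa[h$k]),
                      aromatic_pos = num(h$j),
                      aromatic = aa[h$j],
                      basic_pos = ifelse(isCrac, num(h$k), num(h$i)),
                      basic = ifelse(isCrac, aa[h$k], aa[h$i]),
                      first = num(h$i), last = num(h$k),
                      stringsAsFactors = FALSE)
    out$motif <- sprintf("%s%d-%s%d-%s%d",
                         aa[h$i], num(h$i), aa[h$j], num(h$j),
                         aa[h$k], num(h$k))
    out[order(out$first, out$last), ]
}

.emptyMotifHits <- function() {
    data.frame(kind = character(), apolar_pos = integer(),
               apolar = character(), aromatic_pos = integer(),
               aromatic = character(), basic_pos = integer(),
               basic = character(), first = integer(), last = integer(),
               motif = character(), stringsAsFactors = FALSE)
}

#' Filter motif hits by a membrane-facing position mask
#'
#' Retains hits whose three anchor positions are all membrane facing.
#' The spacer-facing condition is applied to anchors only because
#' per-spacer-residue exposure data is rarely available; pass
#' `fullSpan = TRUE` to require every position of the motif span to be
#' in the mask.
#'
#' @param hits Output of [scanMotifs()].
#' @param membraneFacing Integer vector of membrane-facing residue
#'   numbers (in the same numbering as the hits).
#' @param fullSpan Require all positions `first..last` in the mask.
#' @return The filtered hits data.frame.
#' @export
maskHits <- function(hits, membraneFacing, fullSpan = FALSE) {
    if (!nrow(hits))
        return(hits)
    keep <- if (fullSpan) {
        vapply(seq_len(nrow(hits)), function(i) {
            all(hits$first[i]:hits$last[i] %in% membraneFacing)
        }, TRUE)
    } else {
        hits$apolar_pos %in% membraneFacing &
            hits$aromatic_pos %in% membraneFacing &
            hits$basic_pos %in% membraneFacing
    }
    hits[keep, , drop = FALSE]
}

#' Scan sequences from a FASTA file for CRAC/CARC motifs
#'
#' @param path FASTA file (amino acids).
#' @param ... Passed to [scanMotifs()].  If a sequence name contains
#'   `"offset=N"`, that offset is used for its numbering.
#' @return data.frame of hits with a `sequence` column.
#' @export
scanMotifsFasta <- function(path, ...) {
    seqs <- Biostrings::readAAStringSet(path)
    out <- lapply(seq_along(seqs), function(i) {
        nm <- names(seqs)[i]
        args <- list(sequence = as.character(seqs[[i]]), ...)
        m <- regmatches(nm, regexpr("offset=\\d+", nm))
        if (length(m) && is.null(args$offset))
            args$offset <- as.integer(sub("offset=", "", m))
        h <- do.call(scanMotifs, args)
        if (nrow(h))
            h$sequence <- sub("\\s.*", "", nm)
        h
    })
    out <- out[vapply(out, nrow, 0L) > 0]
    if (!length(out)) {
        e <- .emptyMotifHits()
        e$sequence <- character()
        return(e)
    }
    do.call(rbind, out)
}
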