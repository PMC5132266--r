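## Topology I/O.  GRO files store nm; everything internal is Angstrom.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Default residue-name to lipid-species map
#'
#' Maps coarse-grained lipid residue names onto the species classes used
#' throughout the package (`CHOL`, `PC`, `PE`).  Unmapped, non-protein
#' residue names are classified `OTHER` with a warning at read time.
#'
#' @return Named character vector (names are residue names).
#' @export
defaultSpeciesMap <- function() {
    c(CHOL = "CHOL", CHOL1 = "CHOL",
      DSPC = "PC", DPPC = "PC", POPC = "PC", DOPC = "PC", DLPC = "PC",
      POPE = "PE", DOPE = "PE", DPPE = "PE", DLPE = "PE")
}

#' Read a residue/lipid species map from a sidecar file
#'
#' Plain text, two whitespace-separated columns: residue name, species.
#'
#' @param path File path.
#' @return Named character vector usable as `speciesMap`.
#' @export
readSpeciesMap <- function(path) {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("name", "species"),
                             stringsAsFactors = FALSE)
    stats::setNames(tab$species, tab$name)
}

## Parse one GRO frame starting at line `at`.  Returns fields plus the
## index of the next unread line.
.parseGroFrame <- function(lines, at, path) {
    if (at > length(lines))
        return(NULL)
    title <- lines[at]
    nat <- suppressWarnings(as.integer(trimws(lines[at + 1L])))
    if (is.na(nat) || nat < 1L)
        stop(sprintf("format error in '%s' at line %d: expected atom count",
                     path, at + 1L))
    if (at + 1L + nat + 1L > length(lines))
        stop(sprintf("format error in '%s': truncated frame at line %d",
                     path, at))
    atl <- lines[at + 1L + seq_len(nat)]
    resid <- suppressWarnings(as.integer(substr(atl, 1L, 5L)))
    resname <- trimws(substr(atl, 6L, 10L))
    atname <- trimws(substr(atl, 11L, 15L))
    x <- suppressWarnings(as.numeric(substr(atl, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(atl, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(atl, 37L, 44L)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
        stop(sprintf("format error in '%s' at line %d: unparseable atom record",
                     path, at + 1L + bad[1]))
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[at + 2L + nat]),
                                                 "\\s+")[[1]]))
    if (length(boxv) < 3L || anyNA(boxv))
        stop(sprintf("format error in '%s' at line %d: bad box line",
                     path, at + 2L + nat))
    if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9))
        stop(sprintf("triclinic box in '%s' is not supported (orthorhombic only)",
                     path))
    tm <- NA_real_
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m) == 1L)
        tm <- as.numeric(sub("t=\\s*", "", m))
    list(resid = resid, resname = resname, atname = atname,
         coords = cbind(x, y, z) * 10, box = boxv[1:3] * 10, time = tm,
         nextAt = at + nat + 3L)
}

#' Read a bead topology from a PDB or GRO file
#'
#' Beads are grouped into residues by consecutive (residue id, residue
#' name) records; residue names found in the species map become lipid
#' molecules, standard amino-acid names become protein residues, and
#' anything else is classified as species `OTHER` with a warning.
#' Because residue numbering may repeat (across monomers or after
#' wrap-around), every protein residue receives a unique sequential
#' `residue_id`; the file numbering is kept in column `resid_orig` and
#' the position within its monomer in `seq_pos`.
#'
#' @param path File path.
#' @param dialect `"gro"` or `"pdb"` (default from the file extension).
#' @param speciesMap Named character vector mapping residue names to
#'   species, see [defaultSpeciesMap()].
#' @param monomerFile Optional sidecar: two columns, residue_id and
#'   monomer label.  Without it, PDB chains define monomers and GRO
#'   topologies get a single monomer `"A"`.
#' @param membraneFacingFile Optional sidecar listing membrane-facing
#'   residue ids (one per line); without it all residues are flagged
#'   membrane facing.
#' @return A [BeadTopology-class].  The first-frame coordinates and box
#'   are attached as attributes `"coords"` and `"box"` (Angstrom).
#' @export
readTopology <- function(path, dialect = NULL,
                         speciesMap = defaultSpeciesMap(),
                         monomerFile = NULL, membraneFacingFile = NULL) {
    if (!file.exists(path))
        stop(sprintf("file '%s' does not exist", path))
    if (is.null(dialect))
        dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
    dialect <- match.arg(dialect, c("gro", "pdb"))
    if (dialect == "gro") {
        lines <- readLines(path)
        if (length(lines) < 3L)
            stop(sprintf("format error in '%s': empty or truncated GRO file", path))
        fr <- .parseGroFrame(lines, 1L, path)
        resid <- fr$resid; resname <- fr$resname
        monomer <- NULL
        coords <- fr$coords; box <- fr$box
        beadName <- fr$atname
    } else {
        pdb <- bio3d::read.pdb(path, verbose = FALSE)
        at <- pdb$atom
        resid <- at$resno
        resname <- toupper(at$resid)
        monomer <- at$chain
        monomer[is.na(monomer)] <- "A"
        coords <- cbind(at$x, at$y, at$z)
        box <- NULL
        beadName <- at$elety
    }
    ## group consecutive beads into molecular units
    brk <- c(TRUE, resid[-1] != resid[-length(resid)] |
                   resname[-1] != resname[-length(resname)])
    unit <- cumsum(brk)
    uFirst <- which(brk)
    uName <- resname[uFirst]
    uResid <- resid[uFirst]
    uMono <- if (is.null(monomer)) rep("A", length(uFirst)) else monomer[uFirst]
    isProt <- uName %in% .AA3
    isLip <- !isProt & uName %in% names(speciesMap)
    unknown <- unique(uName[!isProt & !isLip])
    if (length(unknown))
        warning(sprintf("residue name(s) %s not in species map: classified OTHER",
                        paste(unknown, collapse = ", ")))
    species <- rep("OTHER", length(uFirst))
    species[isLip] <- unname(speciesMap[uName[isLip]])

    protIdx <- which(isProt)
    residueId <- seq_along(protIdx)
    resDf <- data.frame(residue_id = residueId,
                        name = uName[protIdx],
                        monomer = uMono[protIdx],
                        membrane_facing = rep(TRUE, length(protIdx)),
                        resid_orig = uResid[protIdx],
                        stringsAsFactors = FALSE)
    resDf$seq_pos <- stats::ave(resDf$residue_id, resDf$monomer,
                                FUN = seq_along)
    lipIdx <- which(!isProt)
    lipDf <- data.frame(molecule_id = seq_along(lipIdx),
                        species = species[lipIdx],
                        name = uName[lipIdx],
                        stringsAsFactors = FALSE)

    owner <- ifelse(isProt[unit], "residue", "lipid")
    ownerId <- integer(length(unit))
    ownerId[owner == "residue"] <- residueId[match(unit[owner == "residue"],
                                                   protIdx)]
    ownerId[owner == "lipid"] <- match(unit[owner == "lipid"], lipIdx)
    beads <- data.frame(index = seq_along(unit), owner = owner,
                        owner_id = ownerId, name = beadName,
                        stringsAsFactors = FALSE)

    if (!is.null(monomerFile)) {
        mo <- utils::read.table(monomerFile, header = FALSE,
                                col.names = c("residue_id", "monomer"),
                                stringsAsFactors = FALSE)
        i <- match(resDf$residue_id, mo$residue_id)
        resDf$monomer[!is.na(i)] <- mo$monomer[i[!is.na(i)]]
        resDf$seq_pos <- stats::ave(resDf$residue_id, resDf$monomer,
                                    FUN = seq_along)
    }
    if (!is.null(membraneFacingFile)) {
        ids <- scan(membraneFacingFile, what = integer(), quiet = TRUE)
        resDf$membrane_facing <- resDf$residue_id %in% ids
    }
    topo <- new("BeadTopology", residues = resDf, lipids = lipDf,
                beads = beads, nBeads = nrow(beads))
    attr(topo, "coords") <- coords
    if (!is.null(box))
        attr(topo, "box") <- box
    topo
}

#' Write a topology plus one coordinate frame as a GRO file
#'
#' @param topology A [BeadTopology-class].
#' @param coords Beads x 3 coordinates in Angstrom.
#' @param box Length-3 box lengths in Angstrom.
#' @param path Output file.
#' @param title Title line; a `t=` tag may encode the frame time (ns).
#' @export
writeTopologyGRO <- function(topology, coords, box, path,
                             title = "cholmap system") {
    con <- file(path, "w")
    on.exit(close(con))
    .writeGroFrame(con, topology, coords, box, title)
    invisible(path)
}

.writeGroFrame <- function(con, topology, coords, box, title) {
    bd <- topology@beads
    n <- nrow(bd)
    resname <- character(n)
    resid <- integer(n)
    isRes <- bd$owner == "residue"
    res <- topology@residues
    lip <- topology@lipids
    resname[isRes] <- res$name[match(bd$owner_id[isRes], res$residue_id)]
    resname[!isRes] <- lip$name[match(bd$owner_id[!isRes], lip$molecule_id)]
    ## sequential per-unit numbering, wrapped to the 5-digit GRO field
    unit <- cumsum(c(TRUE, bd$owner[-1] != bd$owner[-n] |
                           bd$owner_id[-1] != bd$owner_id[-n]))
    resid <- unit %% 100000L
    atname <- bd$name
    if (is.null(atname))
        atname <- "BB"
    writeLines(title, con)
    writeLines(sprintf("%5d", n), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid, substr(resname, 1, 5), substr(atname, 1, 5),
                     seq_len(n) %% 100000L,
                     coords[, 1] / 10, coords[, 2] / 10, coords[, 3] / 10)
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       box[1] / 10, box[2] / 10, box[3] / 10), con)
}
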