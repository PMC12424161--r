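#' @include AllClasses.R
NULL

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.TWO_LETTER_ELEMENTS <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA",
                          "CU", "NI", "CO", "SE", "SI", "AL", "LI", "BE",
                          "HG", "CD", "AS", "KR", "XE")

## Read text lines from a possibly gzipped file.
.readTextLines <- function(path) {
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
}

## Derive an element symbol from a PDB atom name ("F12" -> "F", "CA" in a
## protein residue -> "C").  Used only when the element column is absent.
.elementFromName <- function(name, protein = FALSE) {
    nm <- toupper(gsub("[^A-Za-z]", "", name))
    if (!nzchar(nm)) return(NA_character_)
    if (protein) return(substr(nm, 1L, 1L))
    two <- substr(nm, 1L, 2L)
    if (nchar(nm) >= 2L && two %in% .TWO_LETTER_ELEMENTS)
        return(paste0(substr(two, 1L, 1L), tolower(substr(two, 2L, 2L))))
    substr(nm, 1L, 1L)
}

.normalizeElement <- function(el) {
    el <- gsub("[^A-Za-z]", "", el)
    ifelse(nzchar(el),
           paste0(toupper(substr(el, 1L, 1L)), tolower(substring(el, 2L))),
           NA_character_)
}

## AutoDock atom-type -> element map for PDBQT files.
.ADTYPE_ELEMENT <- c(A = "C", C = "C", N = "N", "NA" = "N", OA = "O",
                     O = "O", SA = "S", S = "S", HD = "H", HS = "H",
                     H = "H", F = "F", CL = "Cl", BR = "Br", I = "I",
                     P = "P", MG = "Mg", MN = "Mn", ZN = "Zn", FE = "Fe")

## Rewrite PDBQT ATOM/HETATM records as PDB records (coordinates only; the
## partial-charge and atom-type columns are dropped, the atom type is mapped
## to an element symbol in columns 77-78).  Only the first MODEL is kept.
.pdbqtToPdbLines <- function(lines) {
    rec <- substr(lines, 1L, 6L)
    model_starts <- which(trimws(rec) == "MODEL")
    if (length(model_starts) > 1L)
        lines <- lines[seq_len(model_starts[2L] - 1L)]
    rec <- substr(lines, 1L, 6L)
    keep <- trimws(rec) %in% c("ATOM", "HETATM")
    lines <- lines[keep]
    vapply(lines, function(ln) {
        base <- formatC(substr(ln, 1L, 66L), width = -66)
        adt <- toupper(trimws(substr(ln, 78L, 79L)))
        el <- .ADTYPE_ELEMENT[match(adt, names(.ADTYPE_ELEMENT))]
        if (is.na(el)) el <- .elementFromName(trimws(substr(ln, 13L, 16L)))
        sprintf("%-66s          %2s", base, toupper(el))
    }, character(1), USE.NAMES = FALSE)
}

.guessFormat <- function(path) {
    p <- sub("\\.gz$", "", tolower(path))
    ext <- tools::file_ext(p)
    switch(ext,
           pdb = , ent = "pdb",
           cif = , mmcif = "cif",
           pdbqt = "pdbqt",
           sdf = , mol = "sdf",
           stop("cannot guess structure format from extension: ", path))
}

## Parse a PDB/mmCIF/PDBQT file into a bio3d-style atom data.frame.
.parseStructure <- function(path, format) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- .readTextLines(path)
    if (format == "pdbqt") {
        lines <- .pdbqtToPdbLines(lines)
        format <- "pdb"
    }
    tmp <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    parsed <- tryCatch(
        if (format == "cif") bio3d::read.cif(tmp) else
            bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE),
        error = function(e) stop("failed to parse '", path, "' as ", format,
                                 ": ", conditionMessage(e), call. = FALSE))
    parsed$atom
}

## Keep the highest-occupancy alternate conformer per atom site; ties go to
## the alphabetically first altloc id ('A' before 'B').
.resolveAltloc <- function(at) {
    alt <- at$alt
    if (is.null(alt) || all(is.na(alt) | alt %in% c("", "."))) return(at)
    occ <- at$o
    occ[is.na(occ)] <- 1
    altkey <- ifelse(is.na(alt) | alt %in% c("", "."), "", alt)
    site <- paste(at$chain, at$resno, at$resid, at$elety)
    ord <- order(site, -occ, altkey)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$resid, at$elety)), ,
             drop = FALSE]
    at[order(at$eleno), , drop = FALSE]
}

.atomTable <- function(at, protein) {
    el <- .normalizeElement(at$elesy)
    miss <- is.na(el) | el == ""
    if (any(miss))
        el[miss] <- vapply(at$elety[miss], .elementFromName,
                           character(1), protein = protein)
    chain <- as.character(at$chain)
    chain[is.na(chain) | chain == ""] <- "A"
    data.frame(serial = as.integer(at$eleno),
               name = as.character(at$elety),
               element = el,
               resname = as.character(at$resid),
               resno = as.integer(at$resno),
               chain = chain,
               x = at$x / 10, y = at$y / 10, z = at$z / 10,
               backbone = protein & as.character(at$elety) %in%
                   .BACKBONE_NAMES,
               stringsAsFactors = FALSE)
}

#' Read a protein-ligand complex
#'
#' Parses a PDB, mmCIF or PDBQT file (optionally gzipped), drops hydrogens,
#' waters, monoatomic ions and any hetero group other than the selected
#' ligand, resolves alternate conformers (highest occupancy, ties to altloc
#' 'A'), and converts coordinates from Angstrom to nm.
#'
#' @param path file path; `.gz` accepted.
#' @param format `"auto"` (from extension), `"pdb"`, `"cif"` or `"pdbqt"`.
#' @param ligand optional ligand component code selecting which hetero group
#'   to keep.
#' @param instance optional 1-based index among matching ligand copies (file
#'   order), for files with several copies of the same component.
#' @param strict if `TRUE` (default) an ambiguity between several ligand
#'   copies is an error; if `FALSE` the first copy in file order is kept.
#' @param remove character vector of residue names removed during cleaning
#'   (waters and common ions/buffer molecules by default).
#' @param entryID,releaseDate optional metadata stored on the object.
#' @return a \linkS4class{PLComplex}
#' @examples
#' cx <- makeToyComplex(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeComplex(cx, f)
#' readComplex(f)
#' @export
readComplex <- function(path, format = c("auto", "pdb", "cif", "pdbqt"),
                        ligand = NULL, instance = NULL, strict = TRUE,
                        remove = c(.WATER_NAMES, .ION_NAMES),
                        entryID = NULL, releaseDate = as.Date(NA)) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") format <- .guessFormat(path)
    if (format == "sdf")
        stop("SDF files hold a ligand only; use readLigandPose()")
    at <- .parseStructure(path, format)
    at <- .resolveAltloc(at)
    el0 <- toupper(.normalizeElement(at$elesy))
    hydro <- (!is.na(el0) & el0 %in% c("H", "D")) |
        ((is.na(el0) | el0 == "") & grepl("^[0-9]*[HD]", toupper(at$elety)))
    at <- at[!hydro, , drop = FALSE]
    is_protein <- at$type == "ATOM" & at$resid %in% .AA3
    prot <- .atomTable(at[is_protein, , drop = FALSE], protein = TRUE)
    het <- at[!is_protein, , drop = FALSE]
    het <- het[!(toupper(het$resid) %in% toupper(remove)), , drop = FALSE]
    ## drop monoatomic hetero groups (ions with nonstandard names)
    if (nrow(het)) {
        grp <- paste(het$chain, het$resno, het$resid)
        sizes <- table(grp)
        het <- het[sizes[grp] > 1L, , drop = FALSE]
    }
    if (!nrow(het))
        stop("no ligand found in '", path, "' after cleaning")
    grp <- paste(het$chain, het$resno, het$resid)
    groups <- unique(grp)
    codes <- vapply(strsplit(groups, " "), function(x)
        paste(x[-(1:2)], collapse = " "), character(1))
    if (!is.null(ligand)) {
        groups <- groups[codes == ligand]
        if (!length(groups))
            stop("no ligand with component code '", ligand, "' in ", path)
    }
    if (!is.null(instance)) {
        if (instance > length(groups))
            stop("ligand instance ", instance, " requested but only ",
                 length(groups), " present")
        groups <- groups[instance]
    }
    if (length(groups) > 1L) {
        if (strict)
            stop(length(groups), " ligand copies in '", path,
                 "'; name one with `ligand`/`instance` or set strict=FALSE")
        groups <- groups[1L]
    }
    lig <- .atomTable(het[grp == groups, , drop = FALSE], protein = FALSE)
    if (is.null(entryID))
        entryID <- toupper(sub("\\.gz$", "", basename(path)))
    new("PLComplex", entryID = entryID,
        ligandID = lig$resname[1L],
        releaseDate = releaseDate,
        proteinAtoms = prot, ligandAtoms = lig,
        sourceFormat = format)
}

#' Read a ligand-only pose file
#'
#' Reads ligand coordinates from a PDBQT/PDB/SDF pose file (as produced by a
#' docking engine) and grafts them onto the protein of a native complex,
#' yielding a predicted \linkS4class{PLComplex}.  If the pose file itself
#' contains protein atoms (e.g. an AF3 model), those are used instead.
#'
#' @param native the native \linkS4class{PLComplex} supplying the protein
#'   when the pose file is ligand-only.
#' @param path pose file path (`.gz` accepted).
#' @param format `"auto"`, `"pdb"`, `"cif"`, `"pdbqt"` or `"sdf"`.
#' @return a \linkS4class{PLComplex}
#' @export
readLigandPose <- function(native, path,
                           format = c("auto", "pdb", "cif", "pdbqt", "sdf")) {
    format <- match.arg(format)
    if (format == "auto") format <- .guessFormat(path)
    if (format == "sdf") {
        sdf <- ChemmineR::read.SDFset(path)[[1L]]
        ab <- ChemmineR::atomblock(sdf)
        el <- .normalizeElement(gsub("_.*$", "", rownames(ab)))
        keep <- !(el %in% c("H", "D"))
        lig <- data.frame(serial = seq_len(sum(keep)),
                          name = paste0(el[keep], seq_len(sum(keep))),
                          element = el[keep],
                          resname = ligandID(native),
                          resno = 1L, chain = "L",
                          x = ab[keep, 1] / 10, y = ab[keep, 2] / 10,
                          z = ab[keep, 3] / 10,
                          backbone = FALSE, stringsAsFactors = FALSE)
        return(new("PLComplex", entryID = entryID(native),
                   ligandID = ligandID(native),
                   releaseDate = releaseDate(native),
                   proteinAtoms = proteinAtoms(native), ligandAtoms = lig,
                   sourceFormat = "sdf"))
    }
    at <- .parseStructure(path, format)
    at <- .resolveAltloc(at)
    is_protein <- at$type == "ATOM" & at$resid %in% .AA3
    if (any(is_protein))
        return(readComplex(path, format = format, strict = FALSE,
                           entryID = entryID(native),
                           releaseDate = releaseDate(native)))
    el <- .normalizeElement(at$elesy)
    at <- at[!(el %in% c("H", "D")), , drop = FALSE]
    lig <- .atomTable(at, protein = FALSE)
    new("PLComplex", entryID = entryID(native), ligandID = ligandID(native),
        releaseDate = releaseDate(native),
        proteinAtoms = proteinAtoms(native), ligandAtoms = lig,
        sourceFormat = format)
}

## Serial numbers above the PDB column width wrap back to 1 (documented
## policy); atom identity on re-read relies on file order, not serials.
.wrapSerial <- function(n) ((seq_len(n) - 1L) %% 99999L) + 1L

#' Write a complex to PDB or mmCIF
#'
#' Coordinates are converted back to Angstrom.  PDB serial numbers wrap at
#' 99999 (atom order, not serials, carries identity on re-read).
#'
#' @param x a \linkS4class{PLComplex}
#' @param path output file path.
#' @param format `"pdb"` or `"cif"`.
#' @return `invisible(path)`
#' @export
writeComplex <- function(x, path, format = c("pdb", "cif")) {
    format <- match.arg(format)
    stopifnot(is(x, "PLComplex"))
    validObject(x)
    prot <- proteinAtoms(x)
    lig <- ligandAtoms(x)
    all_at <- rbind(cbind(prot, type = "ATOM"), cbind(lig, type = "HETATM"))
    n <- nrow(all_at)
    serial <- .wrapSerial(n)
    if (format == "pdb") {
        bio3d::write.pdb(file = path,
                         type = all_at$type,
                         xyz = as.numeric(t(as.matrix(
                             all_at[, c("x", "y", "z")] * 10))),
                         resno = all_at$resno, resid = all_at$resname,
                         eleno = serial, elety = all_at$name,
                         chain = all_at$chain, elesy = all_at$element,
                         o = rep(1, n), b = rep(0, n))
    } else {
        ## minimal PDBx/mmCIF atom_site category in the canonical wwPDB
        ## column order
        hdr <- c(sprintf("data_%s", ifelse(is.na(entryID(x)), "XXXX",
                                           entryID(x))),
                 "#", "loop_",
                 paste0("_atom_site.",
                        c("group_PDB", "id", "type_symbol", "label_atom_id",
                          "label_alt_id", "label_comp_id", "label_asym_id",
                          "label_entity_id", "label_seq_id",
                          "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                          "Cartn_z", "occupancy", "B_iso_or_equiv",
                          "pdbx_formal_charge", "auth_seq_id",
                          "auth_comp_id", "auth_asym_id", "auth_atom_id",
                          "pdbx_PDB_model_num")))
        rows <- sprintf(
            paste("%-6s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00",
                  "? %d %s %s %s 1"),
            all_at$type, serial, all_at$element, all_at$name,
            all_at$resname, all_at$chain, all_at$resno,
            all_at$x * 10, all_at$y * 10, all_at$z * 10,
            all_at$resno, all_at$resname, all_at$chain, all_at$name)
        writeLines(c(hdr, rows, "#"), path)
    }
    invisible(path)
}

#' Define the binding pocket of a native complex
#'
#' The pocket is the set of protein backbone heavy atoms whose distance to
#' the geometric (unweighted) centre of the ligand heavy atoms is at most
#' `cutoff`; the boundary is inclusive.  The pocket is always anchored on
#' the native structure and transferred to predictions through an atom
#' correspondence.
#'
#' @param native a native \linkS4class{PLComplex}.
#' @param cutoff pocket radius in nm (default 1.0).
#' @return a \linkS4class{PocketSelection}; empty (with a warning) when no
#'   backbone atom lies within the cutoff.
#' @export
definePocket <- function(native, cutoff = 1.0) {
    stopifnot(is(native, "PLComplex"), cutoff > 0)
    lig <- as.matrix(ligandAtoms(native)[, c("x", "y", "z")])
    centroid <- colMeans(lig)
    prot <- proteinAtoms(native)
    bb <- prot[prot$backbone, , drop = FALSE]
    if (!nrow(bb)) stop("native complex has no backbone heavy atoms")
    d <- sqrt(colSums((t(as.matrix(bb[, c("x", "y", "z")])) - centroid)^2))
    sel <- bb[d <= cutoff, c("chain", "resno", "name"), drop = FALSE]
    rownames(sel) <- NULL
    if (!nrow(sel))
        warning("empty pocket: no backbone heavy atom within ", cutoff,
                " nm of the ligand centroid")
    new("PocketSelection", atomKeys = sel, cutoff = cutoff,
        centroid = as.numeric(centroid))
}

## Resolve pocket atom keys to row indices of a protein atom table.
.pocketRows <- function(pocket, atoms) {
    key <- paste(atoms$chain, atoms$resno, atoms$name)
    match(paste(pocket@atomKeys$chain, pocket@atomKeys$resno,
                pocket@atomKeys$name), key)
}
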