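#' @include AllClasses.R structure-io.R
NULL

## Covalent radii (nm) for distance-based bond perception.
.COV_RADII <- c(H = 0.031, C = 0.076, N = 0.071, O = 0.066, F = 0.057,
                P = 0.107, S = 0.105, Cl = 0.102, Br = 0.120, I = 0.139)

#' Infer ligand bonds from coordinates
#'
#' Distance-based bond perception: two heavy atoms are bonded when their
#' separation is at most 1.25 times the sum of their covalent radii.  Used
#' to build a ligand topology when no SDF/SMILES graph is supplied.
#'
#' @param atoms ligand atom table (as from [ligandAtoms()]).
#' @return data.frame with columns i, j, order (all 1), aromatic (FALSE).
#' @export
inferBonds <- function(atoms) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    r <- .COV_RADII[atoms$element]
    r[is.na(r)] <- 0.09
    n <- nrow(xyz)
    out <- list()
    for (i in seq_len(max(0L, n - 1L))) {
        d <- sqrt(colSums((t(xyz[(i + 1L):n, , drop = FALSE]) - xyz[i, ])^2))
        j <- which(d <= 1.25 * (r[i] + r[(i + 1L):n])) + i
        if (length(j))
            out[[length(out) + 1L]] <- data.frame(i = i, j = j)
    }
    b <- if (length(out)) do.call(rbind, out) else
        data.frame(i = integer(), j = integer())
    b$order <- rep(1, nrow(b))
    b$aromatic <- rep(FALSE, nrow(b))
    b
}

.residueTable <- function(atoms) {
    key <- paste(atoms$chain, atoms$resno)
    first <- !duplicated(key)
    data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
               resname = atoms$resname[first], stringsAsFactors = FALSE)
}

.oneLetter <- function(resnames) {
    aa <- bio3d::aa321(resnames)
    aa[is.na(aa) | aa == ""] <- "X"
    aa
}

#' Map protein atoms between native and predicted complexes
#'
#' Residues are paired by global pairwise sequence alignment of the
#' one-letter sequences (identity scoring, affine gaps: open 10, extend
#' 0.5); backbone heavy atoms are then paired within aligned residues by
#' atom name.  Robust to residue renumbering and chain renaming; unaligned
#' residues (e.g. missing termini) are simply left unpaired.
#'
#' @param native,predicted \linkS4class{PLComplex} objects.
#' @param minIdentity minimum sequence identity over aligned positions
#'   below which the pairing is refused (default 0.9), guarding against
#'   evaluating the wrong pair of files.
#' @return data.frame with columns native, predicted: row indices into the
#'   protein atom tables.
#' @export
mapProteinAtoms <- function(native, predicted, minIdentity = 0.9) {
    natA <- proteinAtoms(native)
    prdA <- proteinAtoms(predicted)
    natR <- .residueTable(natA)
    prdR <- .residueTable(prdA)
    s1 <- paste(.oneLetter(natR$resname), collapse = "")
    s2 <- paste(.oneLetter(prdR$resname), collapse = "")
    letters_all <- unique(strsplit(paste0(s1, s2), "")[[1]])
    mat <- matrix(-1, length(letters_all), length(letters_all),
                  dimnames = list(letters_all, letters_all))
    diag(mat) <- 1
    aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 10, gapExtension = 0.5)
    a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    i1 <- 0L; i2 <- 0L
    pairs <- matrix(0L, nrow = 0L, ncol = 2L)
    matches <- 0L
    for (k in seq_along(a1)) {
        g1 <- a1[k] == "-"; g2 <- a2[k] == "-"
        if (!g1) i1 <- i1 + 1L
        if (!g2) i2 <- i2 + 1L
        if (!g1 && !g2) {
            pairs <- rbind(pairs, c(i1, i2))
            if (a1[k] == a2[k]) matches <- matches + 1L
        }
    }
    if (!nrow(pairs))
        stop("sequence alignment produced no aligned residues")
    identity <- matches / nrow(pairs)
    if (identity < minIdentity)
        stop(sprintf(paste0("aligned sequence identity %.1f%% below %.0f%%;",
                            " are these the same protein?"),
                     100 * identity, 100 * minIdentity))
    natKey <- paste(natA$chain, natA$resno)
    prdKey <- paste(prdA$chain, prdA$resno)
    natResKey <- paste(natR$chain, natR$resno)
    prdResKey <- paste(prdR$chain, prdR$resno)
    out <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        ri <- which(natKey == natResKey[pairs[k, 1L]] & natA$backbone)
        rj <- which(prdKey == prdResKey[pairs[k, 2L]] & prdA$backbone)
        m <- match(natA$name[ri], prdA$name[rj])
        ok <- !is.na(m)
        if (any(ok))
            out[[k]] <- data.frame(native = ri[ok], predicted = rj[m[ok]])
    }
    res <- do.call(rbind, out)
    if (is.null(res)) data.frame(native = integer(), predicted = integer())
    else res
}

.elementMultisetEqual <- function(a, b) {
    ta <- table(a); tb <- table(b)
    length(ta) == length(tb) && setequal(names(ta), names(tb)) &&
        all(ta[names(tb)] == tb)
}

## Base ligand pairing: by unique atom names when possible, else file order
## within each element class.
.ligandBasePairs <- function(natL, prdL) {
    if (!anyDuplicated(natL$name) && !anyDuplicated(prdL$name) &&
        setequal(natL$name, prdL$name)) {
        data.frame(native = seq_len(nrow(natL)),
                   predicted = match(natL$name, prdL$name))
    } else {
        pred_idx <- integer(nrow(natL))
        for (el in unique(natL$element)) {
            ni <- which(natL$element == el)
            pj <- which(prdL$element == el)
            pred_idx[ni] <- pj[seq_along(ni)]
        }
        data.frame(native = seq_len(nrow(natL)), predicted = pred_idx)
    }
}

.ligandGraph <- function(atoms, bonds) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(atoms) -
                                         igraph::vcount(g)))
    g
}

#' Map ligand atoms between native and predicted complexes
#'
#' `name_order` pairs atoms by name (falling back to file order within each
#' element when names are absent or duplicated).  `symmetry_min` additionally
#' enumerates the automorphisms of the ligand chemical graph (element- and
#' adjacency-preserving, via VF2) and returns the pairing that minimises the
#' ligand-aligned RMSD — so chemically equivalent atoms, such as the three
#' fluorines of a terminal CF3 group, are interchangeable.
#'
#' @param native,predicted \linkS4class{PLComplex} objects with ligands of
#'   identical element composition.
#' @param mode `"name_order"` (default, matches engine atom-order output) or
#'   `"symmetry_min"`.
#' @param topology optional \linkS4class{MoleculeGraph} whose atom order
#'   matches the native ligand atom table; inferred from native coordinates
#'   ([inferBonds()]) when omitted.
#' @param autLimit automorphism-count cap; beyond it the function falls back
#'   to `name_order` with a warning (default 10000).
#' @return data.frame with columns native, predicted: row indices into the
#'   ligand atom tables.
#' @export
mapLigandAtoms <- function(native, predicted,
                           mode = c("name_order", "symmetry_min"),
                           topology = NULL, autLimit = 10000) {
    mode <- match.arg(mode)
    natL <- ligandAtoms(native)
    prdL <- ligandAtoms(predicted)
    if (nrow(natL) != nrow(prdL) ||
        !.elementMultisetEqual(natL$element, prdL$element))
        stop("incompatible ligands: element compositions differ")
    base <- .ligandBasePairs(natL, prdL)
    if (mode == "name_order") return(base)
    bonds <- if (is.null(topology)) inferBonds(natL) else topology@bonds
    if (!nrow(bonds)) return(base)
    g <- .ligandGraph(natL, bonds)
    col <- as.integer(factor(natL$element))
    auts <- igraph::isomorphisms(g, g, method = "vf2",
                                 vertex.color1 = col, vertex.color2 = col)
    if (length(auts) > autLimit) {
        warning(length(auts), " automorphisms exceed limit ", autLimit,
                "; falling back to name_order")
        return(base)
    }
    natXYZ <- as.matrix(natL[, c("x", "y", "z")])
    prdXYZ <- as.matrix(prdL[base$predicted, c("x", "y", "z")])
    best <- base
    best_rmsd <- Inf
    for (a in auts) {
        perm <- as.integer(a)
        nat_perm <- natXYZ[perm, , drop = FALSE]
        r <- if (nrow(natXYZ) >= 3L)
            kabschSuperpose(prdXYZ, nat_perm)$rmsd
        else .rmsd(prdXYZ, nat_perm)
        if (r < best_rmsd - 1e-12) {
            best_rmsd <- r
            best <- data.frame(native = perm, predicted = base$predicted)
        }
    }
    best
}

#' Build a full native-predicted atom correspondence
#'
#' @inheritParams mapLigandAtoms
#' @param ligandMode ligand pairing mode, see [mapLigandAtoms()].
#' @param minIdentity see [mapProteinAtoms()].
#' @return an \linkS4class{AtomCorrespondence}
#' @export
buildCorrespondence <- function(native, predicted,
                                ligandMode = c("name_order", "symmetry_min"),
                                topology = NULL, minIdentity = 0.9,
                                autLimit = 10000) {
    ligandMode <- match.arg(ligandMode)
    new("AtomCorrespondence",
        proteinPairs = mapProteinAtoms(native, predicted, minIdentity),
        ligandPairs = mapLigandAtoms(native, predicted, ligandMode,
                                     topology, autLimit),
        method = ligandMode)
}
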