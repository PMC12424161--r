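#' @include AllClasses.R
NULL

.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, H = 1, B = 3, Si = 4)

## legacy SDF atom-block charge codes -> formal charges
.SDF_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

#' Construct a MoleculeGraph
#'
#' @param elements character vector of element symbols.
#' @param bonds data.frame with columns i, j, order (4 = aromatic); an
#'   `aromatic` column is added if absent.
#' @param charges integer formal charges (default 0).
#' @param name,source metadata.
#' @return a \linkS4class{MoleculeGraph} with aromaticity perceived.
#' @export
moleculeGraph <- function(elements, bonds, charges = 0, name = "",
                          source = "smiles") {
    atoms <- data.frame(element = as.character(elements),
                        aromatic = FALSE,
                        charge = as.integer(rep_len(charges,
                                                    length(elements))),
                        stringsAsFactors = FALSE)
    if (is.null(bonds$aromatic)) bonds$aromatic <- bonds$order == 4
    mol <- new("MoleculeGraph", atoms = atoms,
               bonds = as.data.frame(bonds), name = name, source = source)
    mol <- .largestFragment(mol)
    .perceiveAromaticity(mol)
}

.molIgraph <- function(mol) {
    g <- igraph::make_empty_graph(n = nrow(mol@atoms), directed = FALSE)
    if (nrow(mol@bonds))
        g <- igraph::add_edges(g, rbind(mol@bonds$i, mol@bonds$j))
    g
}

## Keep the largest connected fragment (warn when several are present).
.largestFragment <- function(mol) {
    if (!nrow(mol@bonds)) return(mol)
    comp <- igraph::components(.molIgraph(mol))
    if (comp$no <= 1L) return(mol)
    warning("molecule '", mol@name, "' has ", comp$no,
            " fragments; classifying the largest")
    keep <- which(comp$membership == which.max(comp$csize))
    idx <- match(seq_len(nrow(mol@atoms)), keep)
    b <- mol@bonds[mol@bonds$i %in% keep & mol@bonds$j %in% keep, ,
                   drop = FALSE]
    b$i <- idx[b$i]; b$j <- idx[b$j]
    new("MoleculeGraph", atoms = mol@atoms[keep, , drop = FALSE],
        bonds = b, name = mol@name, source = mol@source)
}

## Minimal-ring aromaticity perception, sufficient for the Ph-F motif:
## for every edge lying on a cycle, take the shortest cycle through it; a
## 5-7 ring whose atoms are all C/N/O/S counts as aromatic when each ring
## carbon has a double (order 2) or aromatic (order 4) bond within the ring.
.perceiveAromaticity <- function(mol) {
    if (!nrow(mol@bonds)) return(mol)
    g <- .molIgraph(mol)
    bridges <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(mol@bonds)), as.integer(bridges))
    arom_atoms <- rep(FALSE, nrow(mol@atoms))
    arom_bonds <- mol@bonds$order == 4
    bond_key <- paste(pmin(mol@bonds$i, mol@bonds$j),
                      pmax(mol@bonds$i, mol@bonds$j))
    for (e in ring_edges) {
        i <- mol@bonds$i[e]; j <- mol@bonds$j[e]
        g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
        sp <- suppressWarnings(igraph::shortest_paths(g2, i, j)$vpath[[1]])
        ring <- as.integer(sp)
        if (length(ring) < 5L || length(ring) > 7L) next
        if (!all(mol@atoms$element[ring] %in% c("C", "N", "O", "S"))) next
        ring_pairs <- paste(pmin(ring, c(ring[-1L], ring[1L])),
                            pmax(ring, c(ring[-1L], ring[1L])))
        ringb <- match(ring_pairs, bond_key)
        orders <- mol@bonds$order[ringb]
        ok <- TRUE
        for (a in ring) {
            if (mol@atoms$element[a] != "C") next
            inc <- ringb[mol@bonds$i[ringb] == a | mol@bonds$j[ringb] == a]
            if (!any(mol@bonds$order[inc] %in% c(2, 4))) { ok <- FALSE; break }
        }
        if (ok) {
            arom_atoms[ring] <- TRUE
            arom_bonds[ringb] <- TRUE
        }
    }
    mol@atoms$aromatic <- arom_atoms
    mol@bonds$aromatic <- arom_bonds
    mol
}

.parseMCHG <- function(lines) {
    chg <- integer()
    for (ln in grep("^M  CHG", lines, value = TRUE)) {
        f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                                 "[[:space:]]+")[[1]])
        n <- f[1L]
        for (k in seq_len(n)) chg[f[2 * k]] <- f[2 * k + 1L]
    }
    chg
}

.sdfToMoleculeGraph <- function(sdf, name, source) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- gsub("_.*$", "", rownames(ab))
    if (!length(el) || !all(grepl("^[A-Za-z]", el)))
        stop("SDF atom block could not be parsed (single-atom molecules ",
             "are not supported by the SDF reader; use moleculeGraph())")
    charge <- rep(0L, nrow(ab))
    if ("C6" %in% colnames(ab)) {
        code <- as.character(ab[, "C6"])
        mapped <- .SDF_CHARGE[code]
        mapped[is.na(mapped)] <- 0
        charge <- as.integer(mapped)
    }
    bonds <- if (is.matrix(bb) && nrow(bb) && ncol(bb) >= 3L)
        data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                   order = as.numeric(bb[, 3L]))
    else
        data.frame(i = integer(), j = integer(), order = numeric())
    moleculeGraph(el, bonds, charge, name = name, source = source)
}

#' Build a molecule graph from an SDF file
#'
#' @param path SDF (V2000) file; the first molecule is used.
#' @param name molecule name (defaults to the file stem).
#' @return a \linkS4class{MoleculeGraph}
#' @export
moleculeFromSDF <- function(path, name = NULL) {
    sdfset <- ChemmineR::read.SDFset(path)
    sdf <- sdfset[[1L]]
    if (is.null(name))
        name <- tools::file_path_sans_ext(basename(path))
    mol <- .sdfToMoleculeGraph(sdf, name, "sdf")
    mchg <- .parseMCHG(.readTextLines(path))
    if (length(mchg)) {
        idx <- which(!is.na(mchg))
        idx <- idx[idx <= nrow(mol@atoms)]
        mol@atoms$charge[idx] <- as.integer(mchg[idx])
    }
    mol
}

#' Build a molecule graph from a SMILES string
#'
#' Conversion goes through OpenBabel (ChemmineOB).
#'
#' @param smiles SMILES string.
#' @param name molecule name.
#' @return a \linkS4class{MoleculeGraph}
#' @export
moleculeFromSMILES <- function(smiles, name = smiles) {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
        stop("SMILES input requires the ChemmineOB package")
    sdf <- ChemmineR::smiles2sdf(smiles)[[1L]]
    .sdfToMoleculeGraph(sdf, name, "smiles")
}

.ccdTable <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- utils::read.delim(
                system.file("extdata", "ccd_smiles.tsv",
                            package = "pfasbench"),
                comment.char = "#", stringsAsFactors = FALSE)
        cache
    }
})

#' Build a molecule graph from a bundled CCD component code
#'
#' The package bundles SMILES for the small set of PFAS component codes used
#' in its worked examples (e.g. 8PF = perfluorooctanoic acid).  Arbitrary
#' CCD lookup is out of scope.
#'
#' @param code CCD component code (e.g. `"8PF"`).
#' @return a \linkS4class{MoleculeGraph}
#' @export
moleculeFromCCD <- function(code) {
    tab <- .ccdTable()
    row <- tab[toupper(tab$code) == toupper(code), , drop = FALSE]
    if (!nrow(row))
        stop("CCD code '", code, "' not in the bundled lookup table (",
             paste(tab$code, collapse = ", "), ")")
    mol <- moleculeFromSMILES(row$smiles[1L], name = row$code[1L])
    mol@source <- "ccd"
    mol
}

.bondOrderSum <- function(mol) {
    bs <- rep(0, nrow(mol@atoms))
    if (nrow(mol@bonds)) {
        ord <- ifelse(mol@bonds$order == 4, 1.5, mol@bonds$order)
        for (k in seq_len(nrow(mol@bonds))) {
            bs[mol@bonds$i[k]] <- bs[mol@bonds$i[k]] + ord[k]
            bs[mol@bonds$j[k]] <- bs[mol@bonds$j[k]] + ord[k]
        }
    }
    bs
}

## Implicit hydrogen count per atom from standard valences, adjusted by
## formal charge (O- carries one bond, N+ four, ...).
.implicitH <- function(mol) {
    val <- .DEFAULT_VALENCE[mol@atoms$element]
    val[is.na(val)] <- 0
    adj <- val + mol@atoms$charge
    pmax(0, round(adj - .bondOrderSum(mol)))
}

.neighborList <- function(mol) {
    n <- nrow(mol@atoms)
    nb <- vector("list", n)
    for (k in seq_len(nrow(mol@bonds))) {
        i <- mol@bonds$i[k]; j <- mol@bonds$j[k]
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
    }
    nb
}

.explicitHCount <- function(mol, nb) {
    vapply(seq_len(nrow(mol@atoms)), function(i)
        sum(mol@atoms$element[nb[[i]]] == "H"), numeric(1))
}

#' Classify PFAS structural motifs
#'
#' Three boolean structural screens:
#' \describe{
#'   \item{oecd}{a saturated, non-aromatic carbon bears at least two
#'     fluorines and no hydrogen — covers both -CF2- and -CF3 groups
#'     (OECD 2021 reading).}
#'   \item{epa_cf2cf}{a saturated CF2 carbon (exactly two fluorines, no
#'     hydrogen) is bonded to another saturated carbon bearing at least one
#'     fluorine (EPA OPPT -CF2-CF< motif).  `epaVariant = "cfcf"` relaxes
#'     this to any two adjacent fluorinated saturated carbons.}
#'   \item{aromatic_f}{an aromatic carbon is bonded to fluorine (-Ph-F).}
#' }
#' `epa_cf2cf` implies `oecd` on any molecule.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @param epaVariant `"cf2cf"` (default, strict) or `"cfcf"`.
#' @return named logical vector `c(oecd=, epa_cf2cf=, aromatic_f=)`
#' @export
classifyMotifs <- function(mol, epaVariant = c("cf2cf", "cfcf")) {
    epaVariant <- match.arg(epaVariant)
    mol <- .largestFragment(mol)
    nb <- .neighborList(mol)
    el <- mol@atoms$element
    nF <- vapply(seq_along(el), function(i) sum(el[nb[[i]]] == "F"),
                 numeric(1))
    nH <- .explicitHCount(mol, nb) + .implicitH(mol)
    bs <- .bondOrderSum(mol)
    deg <- lengths(nb)
    saturatedC <- el == "C" & !mol@atoms$aromatic & bs == deg  # all single
    oecd <- any(saturatedC & nF >= 2 & nH == 0)
    cf2 <- saturatedC & nF == 2 & nH == 0
    cfx <- saturatedC & nF >= 1
    pairHit <- function(setA, setB) {
        if (!nrow(mol@bonds)) return(FALSE)
        any((setA[mol@bonds$i] & setB[mol@bonds$j]) |
            (setA[mol@bonds$j] & setB[mol@bonds$i]))
    }
    epa <- if (epaVariant == "cf2cf") pairHit(cf2, cfx) else
        pairHit(cfx, cfx)
    aromF <- pairHit(el == "F", mol@atoms$aromatic & el == "C")
    c(oecd = oecd, epa_cf2cf = epa, aromatic_f = aromF)
}

#' Carbon chain length
#'
#' Number of carbons on the longest simple path through carbon-carbon bonds
#' (the carboxyl/head carbon counts), computed by exhaustive depth-first
#' search on the carbon subgraph.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @return integer chain length; 0 for a molecule without carbon.
#' @export
chainLength <- function(mol) {
    mol <- .largestFragment(mol)
    carbons <- which(mol@atoms$element == "C")
    if (!length(carbons)) return(0L)
    idx <- match(seq_len(nrow(mol@atoms)), carbons)
    nbAll <- .neighborList(mol)
    nb <- lapply(carbons, function(i) {
        cc <- nbAll[[i]][mol@atoms$element[nbAll[[i]]] == "C"]
        idx[cc]
    })
    n <- length(carbons)
    best <- 1L
    visited <- rep(FALSE, n)
    dfs <- function(v, depth) {
        visited[v] <<- TRUE
        if (depth > best) best <<- depth
        for (w in nb[[v]])
            if (!visited[w]) dfs(w, depth + 1L)
        visited[v] <<- FALSE
    }
    for (s in seq_len(n)) dfs(s, 1L)
    as.integer(best)
}

#' Net-charge category at physiological pH
#'
#' A deliberately simple rule-based formal-charge model at pH 7.4:
#' carboxylic, sulfonic/sulfate and phosphonate acid groups contribute -1
#' each; aliphatic (non-amide, non-aromatic) amines contribute +1; formal
#' charges on atoms not covered by these patterns (e.g. quaternary ammonium)
#' are added as-is.  The sign of the sum gives the category.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @param pH considered pH; only 7.4-style behaviour is modelled and a value
#'   outside (5, 9) warns.
#' @return `"negative"`, `"neutral"` or `"positive"`
#' @export
chargeCategory <- function(mol, pH = 7.4) {
    if (pH < 5 || pH > 9)
        warning("charge rules are calibrated for physiological pH; got ", pH)
    mol <- .largestFragment(mol)
    nb <- .neighborList(mol)
    el <- mol@atoms$element
    implH <- .implicitH(mol)
    explH <- .explicitHCount(mol, nb)
    bondOrder <- function(i, j) {
        k <- which((mol@bonds$i == i & mol@bonds$j == j) |
                   (mol@bonds$i == j & mol@bonds$j == i))
        if (length(k)) mol@bonds$order[k[1L]] else 0
    }
    heavyNb <- lapply(nb, function(v) v[el[v] != "H"])
    ## terminal acidic oxygen: one heavy neighbour, single bond, carries H
    ## or a negative formal charge
    acidicO <- vapply(seq_along(el), function(i) {
        el[i] == "O" && length(heavyNb[[i]]) == 1L &&
            bondOrder(i, heavyNb[[i]][1L]) == 1 &&
            (implH[i] + explH[i] > 0 || mol@atoms$charge[i] < 0)
    }, logical(1))
    doubleO <- function(i)
        sum(vapply(heavyNb[[i]], function(j)
            el[j] == "O" && bondOrder(i, j) == 2, logical(1)))
    nTermAcid <- function(i) sum(acidicO[heavyNb[[i]]])
    net <- 0
    counted <- rep(FALSE, length(el))
    for (i in seq_along(el)) {
        hit <- switch(el[i],
            C = doubleO(i) >= 1 && nTermAcid(i) >= 1,
            S = doubleO(i) >= 2 && nTermAcid(i) >= 1,
            P = doubleO(i) >= 1 && nTermAcid(i) >= 1,
            FALSE)
        if (isTRUE(hit)) {
            net <- net - 1
            counted[i] <- TRUE
            oxy <- heavyNb[[i]][el[heavyNb[[i]]] == "O"]
            counted[oxy] <- TRUE
        }
    }
    isAmide <- function(i) any(vapply(heavyNb[[i]], function(j)
        el[j] == "C" && doubleO(j) >= 1, logical(1)))
    for (i in which(el == "N")) {
        if (counted[i] || mol@atoms$aromatic[i]) next
        allSingle <- all(vapply(heavyNb[[i]], function(j)
            bondOrder(i, j) == 1, logical(1)))
        aromNb <- any(mol@atoms$aromatic[heavyNb[[i]]])
        if (allSingle && length(heavyNb[[i]]) <= 3L && !isAmide(i) &&
            !aromNb) {
            net <- net + 1
            counted[i] <- TRUE
        }
    }
    net <- net + sum(mol@atoms$charge[!counted])
    if (net < 0) "negative" else if (net > 0) "positive" else "neutral"
}

#' Full PFAS profile of a ligand
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @param epaVariant see [classifyMotifs()].
#' @return one-row data.frame with columns oecd, epa_cf2cf, aromatic_f,
#'   chain_length, charge_category.
#' @export
pfasProfile <- function(mol, epaVariant = "cf2cf") {
    m <- classifyMotifs(mol, epaVariant)
    data.frame(name = mol@name,
               oecd = unname(m["oecd"]),
               epa_cf2cf = unname(m["epa_cf2cf"]),
               aromatic_f = unname(m["aromatic_f"]),
               chain_length = chainLength(mol),
               charge_category = chargeCategory(mol),
               stringsAsFactors = FALSE)
}
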