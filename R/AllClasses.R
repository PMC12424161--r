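#' @import methods
NULL

## Atom tables are plain data.frames with a fixed column set; all coordinates
## are stored in nanometres and only heavy atoms (element != H) are retained.
.ATOM_COLS <- c("serial", "name", "element", "resname", "resno", "chain",
                "x", "y", "z", "backbone")

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

## Residue/ion names stripped during cleaning (configurable in readComplex).
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP", "TIP3")
.ION_NAMES <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "CU", "NI",
                "CO", "CD", "HG", "BR", "IOD", "CS", "LI", "RB", "SR", "BA",
                "SO4", "PO4", "NO3", "ACT", "GOL", "EDO", "PEG", "DMS")

.checkAtomTable <- function(df, what) {
    msgs <- character()
    missing_cols <- setdiff(.ATOM_COLS, names(df))
    if (length(missing_cols))
        return(sprintf("%s atom table lacks columns: %s", what,
                       paste(missing_cols, collapse = ", ")))
    xyz <- as.matrix(df[, c("x", "y", "z")])
    if (nrow(df) && !all(is.finite(xyz)))
        msgs <- c(msgs, sprintf("%s coordinates must be finite", what))
    if (nrow(df) && any(toupper(df$element) %in% c("H", "D")))
        msgs <- c(msgs, sprintf("%s atoms must be heavy (no H/D)", what))
    if (nrow(df) && any(df$backbone & !(df$name %in% .BACKBONE_NAMES)))
        msgs <- c(msgs, sprintf("%s backbone flag allowed only for N/CA/C/O",
                                what))
    msgs
}

#' Protein-ligand complex
#'
#' Container for one cleaned protein-PFAS complex: an ordered heavy-atom
#' table for the protein, one for the single ligand instance, and entry
#' metadata.  Coordinates are in nanometres.  Waters, ions and any hetero
#' group other than the selected ligand are removed at construction time by
#' [readComplex()].
#'
#' @slot entryID character entry identifier (e.g. a PDB id).
#' @slot ligandID character ligand component code.
#' @slot releaseDate `Date` of deposition/release, or `NA`.
#' @slot proteinAtoms data.frame of protein heavy atoms.
#' @slot ligandAtoms data.frame of ligand heavy atoms.
#' @slot sourceFormat character, one of `"pdb"`, `"cif"`, `"pdbqt"`, `"sdf"`,
#'   `"synthetic"`.
#' @name PLComplex-class
#' @aliases PLComplex
#' @exportClass PLComplex
setClass("PLComplex",
    representation(entryID = "character",
                   ligandID = "character",
                   releaseDate = "ANY",
                   proteinAtoms = "data.frame",
                   ligandAtoms = "data.frame",
                   sourceFormat = "character"),
    prototype(entryID = NA_character_, ligandID = NA_character_,
              releaseDate = as.Date(NA), sourceFormat = "synthetic"))

setValidity("PLComplex", function(object) {
    msgs <- character()
    if (!nrow(object@proteinAtoms))
        msgs <- c(msgs, "protein must contain at least one heavy atom")
    if (!nrow(object@ligandAtoms))
        msgs <- c(msgs, "ligand must contain at least one heavy atom")
    msgs <- c(msgs,
              .checkAtomTable(object@proteinAtoms, "protein"),
              .checkAtomTable(object@ligandAtoms, "ligand"))
    if (nrow(object@ligandAtoms)) {
        lig <- object@ligandAtoms
        if (any(toupper(lig$resname) %in% .WATER_NAMES))
            msgs <- c(msgs, "water kept as ligand")
        if (length(unique(paste(lig$chain, lig$resno, lig$resname))) > 1L)
            msgs <- c(msgs, "more than one ligand instance retained")
        if (any(lig$backbone))
            msgs <- c(msgs, "ligand atoms cannot carry backbone flags")
    }
    if (length(msgs)) msgs else TRUE
})

#' Binding-pocket selection
#'
#' The binding pocket is the set of protein backbone heavy atoms whose
#' distance to the geometric centre of the native ligand heavy atoms is at
#' most `cutoff` (inclusive).  Atoms are referenced by key
#' (chain, residue number, atom name) so a selection made on the native
#' structure can be transferred to a predicted one through a correspondence.
#'
#' @slot atomKeys data.frame with columns chain, resno, name.
#' @slot cutoff numeric cutoff in nm.
#' @slot centroid numeric(3) ligand heavy-atom centroid in nm.
#' @name PocketSelection-class
#' @aliases PocketSelection
#' @exportClass PocketSelection
setClass("PocketSelection",
    representation(atomKeys = "data.frame", cutoff = "numeric",
                   centroid = "numeric"))

setValidity("PocketSelection", function(object) {
    msgs <- character()
    if (!all(c("chain", "resno", "name") %in% names(object@atomKeys)))
        msgs <- c(msgs, "atomKeys needs columns chain, resno, name")
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
        object@cutoff <= 0)
        msgs <- c(msgs, "cutoff must be a positive length in nm")
    if (length(object@centroid) != 3L || !all(is.finite(object@centroid)))
        msgs <- c(msgs, "centroid must be a finite 3-vector")
    if (nrow(object@atomKeys) &&
        !all(object@atomKeys$name %in% .BACKBONE_NAMES))
        msgs <- c(msgs, "pocket atoms must be backbone heavy atoms")
    if (length(msgs)) msgs else TRUE
})

#' Native-predicted atom correspondence
#'
#' A validated one-to-one pairing between atoms of a native and a predicted
#' complex, held separately for the protein and the ligand.  Pairs are row
#' indices into the respective atom tables of the two [PLComplex] objects the
#' correspondence was built from.
#'
#' @slot proteinPairs data.frame with columns native, predicted (row indices
#'   into the protein atom tables).
#' @slot ligandPairs data.frame with columns native, predicted (row indices
#'   into the ligand atom tables).
#' @slot method character: `"name_order"`, `"sequence_aligned"` or
#'   `"symmetry_min"`.
#' @name AtomCorrespondence-class
#' @aliases AtomCorrespondence
#' @exportClass AtomCorrespondence
setClass("AtomCorrespondence",
    representation(proteinPairs = "data.frame", ligandPairs = "data.frame",
                   method = "character"))

setValidity("AtomCorrespondence", function(object) {
    msgs <- character()
    for (nm in c("proteinPairs", "ligandPairs")) {
        p <- slot(object, nm)
        if (!all(c("native", "predicted") %in% names(p))) {
            msgs <- c(msgs, sprintf("%s needs columns native, predicted", nm))
            next
        }
        if (anyDuplicated(p$native) || anyDuplicated(p$predicted))
            msgs <- c(msgs, sprintf("%s pairing must be injective both ways",
                                    nm))
    }
    if (length(msgs)) msgs else TRUE
})

#' Metrics for one predicted pose
#'
#' The four alignment-reference heavy-atom RMSDs (nm) of a predicted pose
#' against its native complex: protein backbone, protein pocket, ligand
#' (ligand-fitted), and pocket-aligned ligand (ligand deviation after a
#' pocket-only superposition, with no further fitting).
#'
#' @slot rmsdBackbone,rmsdPocket,rmsdLigand,rmsdPocketAlignedLigand numeric
#'   RMSDs in nm.
#' @slot pocketCoverage numeric fraction of native pocket atoms resolvable in
#'   the prediction.
#' @slot rank integer pose rank as produced by the predicting engine.
#' @slot methodLabel character label of the predicting engine.
#' @name PoseMetrics-class
#' @aliases PoseMetrics
#' @exportClass PoseMetrics
setClass("PoseMetrics",
    representation(rmsdBackbone = "numeric", rmsdPocket = "numeric",
                   rmsdLigand = "numeric",
                   rmsdPocketAlignedLigand = "numeric",
                   pocketCoverage = "numeric", rank = "integer",
                   methodLabel = "character"),
    prototype(pocketCoverage = 1, rank = 1L, methodLabel = ""))

setValidity("PoseMetrics", function(object) {
    vals <- c(object@rmsdBackbone, object@rmsdPocket, object@rmsdLigand,
              object@rmsdPocketAlignedLigand)
    msgs <- character()
    if (length(vals) != 4L || !all(is.finite(vals)) || any(vals < 0))
        msgs <- c(msgs, "all four RMSDs must be finite and >= 0")
    if (length(object@rank) != 1L || is.na(object@rank) || object@rank < 1L)
        msgs <- c(msgs, "rank must be an integer >= 1")
    if (length(object@pocketCoverage) != 1L ||
        object@pocketCoverage < 0 || object@pocketCoverage > 1)
        msgs <- c(msgs, "pocketCoverage must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Ligand molecular graph
#'
#' Chemical graph of a ligand: atoms (element, aromatic flag, formal charge)
#' and bonds (endpoint indices, order, aromatic flag).  Built from SDF files,
#' SMILES strings or a bundled CCD-code lookup; hydrogens may be implicit
#' (they are reconstructed from standard valences where needed).
#'
#' @slot atoms data.frame with columns element, aromatic, charge.
#' @slot bonds data.frame with columns i, j, order, aromatic.
#' @slot name character molecule name.
#' @slot source character: `"sdf"`, `"smiles"` or `"ccd"`.
#' @name MoleculeGraph-class
#' @aliases MoleculeGraph
#' @exportClass MoleculeGraph
setClass("MoleculeGraph",
    representation(atoms = "data.frame", bonds = "data.frame",
                   name = "character", source = "character"),
    prototype(name = "", source = "smiles"))

setValidity("MoleculeGraph", function(object) {
    msgs <- character()
    if (!all(c("element", "aromatic", "charge") %in% names(object@atoms)))
        msgs <- c(msgs, "atoms needs columns element, aromatic, charge")
    if (!all(c("i", "j", "order", "aromatic") %in% names(object@bonds)))
        msgs <- c(msgs, "bonds needs columns i, j, order, aromatic")
    else if (nrow(object@bonds)) {
        n <- nrow(object@atoms)
        if (any(object@bonds$i < 1L | object@bonds$i > n |
                object@bonds$j < 1L | object@bonds$j > n))
            msgs <- c(msgs, "bond endpoints out of range")
    }
    if (length(msgs)) msgs else TRUE
})

#' Per-pose evaluation table
#'
#' Tidy table of per-system, per-method, per-rank pose metrics feeding the
#' statistics layer.  One row per evaluated pose; the four RMSD columns are
#' in nm.  Ranks must be contiguous from 1 within each (entry, method).
#'
#' @slot records data.frame with columns entry_id, method, rank,
#'   rmsd_backbone, rmsd_pocket, rmsd_ligand, rmsd_pal, and optionally
#'   split, charge_category, oecd, epa_cf2cf, aromatic_f, chain_length,
#'   pocket_coverage.
#' @name EvaluationTable-class
#' @aliases EvaluationTable
#' @exportClass EvaluationTable
setClass("EvaluationTable", representation(records = "data.frame"))

.EVAL_COLS <- c("entry_id", "method", "rank", "rmsd_backbone", "rmsd_pocket",
                "rmsd_ligand", "rmsd_pal")

setValidity("EvaluationTable", function(object) {
    df <- object@records
    msgs <- character()
    missing_cols <- setdiff(.EVAL_COLS, names(df))
    if (length(missing_cols))
        return(sprintf("records lacks columns: %s",
                       paste(missing_cols, collapse = ", ")))
    key <- paste(df$entry_id, df$method, df$rank)
    if (anyDuplicated(key))
        msgs <- c(msgs, "(entry_id, method, rank) must be unique")
    rk <- split(df$rank, paste(df$entry_id, df$method))
    bad <- vapply(rk, function(r) !setequal(r, seq_len(max(r))), logical(1))
    if (any(bad))
        msgs <- c(msgs, "ranks must be contiguous from 1 per (entry, method)")
    if (length(msgs)) msgs else TRUE
})

#' Perturbation specification for synthetic poses
#'
#' Describes one controlled error mode applied to a native complex to
#' manufacture a "predicted" pose.  `magnitude` is mode-specific: nm for
#' `global_rigid` (translation; the rotation angle is drawn by the seed),
#' `ligand_rigid` (translation distance) and `pocket_noise` (per-coordinate
#' Gaussian sigma); degrees for `ligand_internal` (torsion kick).
#'
#' @slot mode character perturbation mode.
#' @slot magnitude numeric, mode-specific units (see above).
#' @slot seed integer RNG seed.
#' @name PerturbationSpec-class
#' @aliases PerturbationSpec
#' @exportClass PerturbationSpec
setClass("PerturbationSpec",
    representation(mode = "character", magnitude = "numeric",
                   seed = "integer"))

.PERTURB_MODES <- c("global_rigid", "ligand_rigid", "ligand_internal",
                    "pocket_noise", "combined")

setValidity("PerturbationSpec", function(object) {
    msgs <- character()
    if (!object@mode %in% .PERTURB_MODES)
        msgs <- c(msgs, sprintf("mode must be one of: %s",
                                paste(.PERTURB_MODES, collapse = ", ")))
    if (length(object@magnitude) != 1L || !is.finite(object@magnitude) ||
        object@magnitude < 0)
        msgs <- c(msgs, "magnitude must be a single number >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Cohort specification for synthetic evaluation tables
#'
#' @slot nSystems integer number of systems generated per split.
#' @slot successProb named numeric vector of per-split success probabilities
#'   for the pocket-aligned ligand criterion (names become split labels).
#' @slot modeMixture named numeric probabilities over perturbation modes
#'   (used by perturbation cohorts), summing to 1.
#' @slot seed integer RNG seed.
#' @name CohortSpec-class
#' @aliases CohortSpec
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(nSystems = "integer", successProb = "numeric",
                   modeMixture = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
    msgs <- character()
    if (object@nSystems < 1L)
        msgs <- c(msgs, "nSystems must be >= 1")
    if (!length(object@successProb) || is.null(names(object@successProb)) ||
        any(object@successProb < 0 | object@successProb > 1))
        msgs <- c(msgs, "successProb must be a named vector of probabilities")
    if (length(object@modeMixture)) {
        if (any(object@modeMixture < 0) ||
            abs(sum(object@modeMixture) - 1) > 1e-8)
            msgs <- c(msgs, "modeMixture must be probabilities summing to 1")
        if (!all(names(object@modeMixture) %in% .PERTURB_MODES))
            msgs <- c(msgs, "modeMixture names must be perturbation modes")
    }
    if (length(msgs)) msgs else TRUE
})
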