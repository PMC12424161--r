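#' @include AllClasses.R
NULL

#' @rdname PLComplex-class
#' @param object,x a \linkS4class{PLComplex}
#' @export
setGeneric("proteinAtoms", function(x) standardGeneric("proteinAtoms"))
#' @rdname PLComplex-class
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))
#' @rdname PLComplex-class
#' @export
setGeneric("entryID", function(x) standardGeneric("entryID"))
#' @rdname PLComplex-class
#' @export
setGeneric("ligandID", function(x) standardGeneric("ligandID"))
#' @rdname PLComplex-class
#' @export
setGeneric("releaseDate", function(x) standardGeneric("releaseDate"))

#' @rdname EvaluationTable-class
#' @param x an \linkS4class{EvaluationTable}
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname PocketSelection-class
#' @param x a \linkS4class{PocketSelection}
#' @export
setGeneric("pocketAtomKeys", function(x) standardGeneric("pocketAtomKeys"))
#' @rdname PocketSelection-class
#' @export
setGeneric("pocketCutoff", function(x) standardGeneric("pocketCutoff"))
#' @rdname PocketSelection-class
#' @export
setGeneric("pocketCentroid", function(x) standardGeneric("pocketCentroid"))

setMethod("proteinAtoms", "PLComplex", function(x) x@proteinAtoms)
setMethod("ligandAtoms", "PLComplex", function(x) x@ligandAtoms)
setMethod("entryID", "PLComplex", function(x) x@entryID)
setMethod("ligandID", "PLComplex", function(x) x@ligandID)
setMethod("releaseDate", "PLComplex", function(x) x@releaseDate)
setMethod("records", "EvaluationTable", function(x) x@records)
setMethod("pocketAtomKeys", "PocketSelection", function(x) x@atomKeys)
setMethod("pocketCutoff", "PocketSelection", function(x) x@cutoff)
setMethod("pocketCentroid", "PocketSelection", function(x) x@centroid)

setMethod("show", "PLComplex", function(object) {
    nres <- length(unique(paste(object@proteinAtoms$chain,
                                object@proteinAtoms$resno)))
    cat(sprintf(paste0("PLComplex '%s' (ligand %s)\n",
                       "  protein: %d heavy atoms, %d residues\n",
                       "  ligand:  %d heavy atoms\n",
                       "  release: %s | source: %s\n"),
                object@entryID, object@ligandID,
                nrow(object@proteinAtoms), nres, nrow(object@ligandAtoms),
                format(object@releaseDate), object@sourceFormat))
})

setMethod("show", "PocketSelection", function(object) {
    cat(sprintf(
        "PocketSelection: %d backbone atoms within %.2f nm of centroid (%s)\n",
        nrow(object@atomKeys), object@cutoff,
        paste(sprintf("%.2f", object@centroid), collapse = ", ")))
})

setMethod("show", "AtomCorrespondence", function(object) {
    cat(sprintf(
        "AtomCorrespondence (%s): %d protein pairs, %d ligand pairs\n",
        object@method, nrow(object@proteinPairs), nrow(object@ligandPairs)))
})

setMethod("show", "PoseMetrics", function(object) {
    cat(sprintf(paste0(
        "PoseMetrics [%s, rank %d]\n",
        "  backbone: %.3f nm | pocket: %.3f nm | ligand: %.3f nm | ",
        "pocket-aligned ligand: %.3f nm\n  pocket coverage: %.0f%%\n"),
        object@methodLabel, object@rank, object@rmsdBackbone,
        object@rmsdPocket, object@rmsdLigand,
        object@rmsdPocketAlignedLigand, 100 * object@pocketCoverage))
})

setMethod("show", "MoleculeGraph", function(object) {
    cat(sprintf("MoleculeGraph '%s' (%s): %d atoms, %d bonds\n",
                object@name, object@source, nrow(object@atoms),
                nrow(object@bonds)))
})

setMethod("show", "EvaluationTable", function(object) {
    df <- object@records
    cat(sprintf(
        "EvaluationTable: %d poses, %d systems, methods: %s\n",
        nrow(df), length(unique(df$entry_id)),
        paste(unique(df$method), collapse = ", ")))
})

#' Construct an EvaluationTable
#'
#' @param records data.frame of per-pose metric rows (see
#'   \linkS4class{EvaluationTable}).
#' @return an \linkS4class{EvaluationTable}
#' @export
EvaluationTable <- function(records) {
    records$rank <- as.integer(records$rank)
    new("EvaluationTable", records = as.data.frame(records))
}

#' Construct a PerturbationSpec
#'
#' @param mode one of `"global_rigid"`, `"ligand_rigid"`,
#'   `"ligand_internal"`, `"pocket_noise"`, `"combined"`.
#' @param magnitude mode-specific magnitude (nm or degrees, see
#'   \linkS4class{PerturbationSpec}).
#' @param seed integer RNG seed.
#' @return a \linkS4class{PerturbationSpec}
#' @export
perturbationSpec <- function(mode, magnitude, seed = 1L) {
    new("PerturbationSpec", mode = mode, magnitude = as.numeric(magnitude),
        seed = as.integer(seed))
}

#' Construct a CohortSpec
#'
#' @param nSystems systems per split.
#' @param successProb named per-split success probabilities for the
#'   pocket-aligned ligand criterion.
#' @param modeMixture named probabilities over perturbation modes (optional).
#' @param seed integer RNG seed.
#' @return a \linkS4class{CohortSpec}
#' @export
cohortSpec <- function(nSystems,
                       successProb = c(Before = 0.745, After = 0.558),
                       modeMixture = numeric(), seed = 1L) {
    new("CohortSpec", nSystems = as.integer(nSystems),
        successProb = successProb, modeMixture = modeMixture,
        seed = as.integer(seed))
}
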