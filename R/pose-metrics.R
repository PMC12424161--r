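#' @include AllClasses.R structure-io.R
NULL

#' Kabsch least-squares superposition
#'
#' Computes the proper rigid transform (rotation + translation) minimising
#' the RMSD between two paired point sets, by singular value decomposition
#' of the cross-covariance matrix.  Reflections are excluded by flipping the
#' sign of the smallest singular vector when the rotation determinant would
#' be negative.
#'
#' @param moving n x 3 matrix of points to transform (nm).
#' @param reference n x 3 matrix of target points (nm), same row pairing.
#' @return list with elements `rotation` (3 x 3, det = +1), `translation`
#'   (length 3), and `rmsd` (nm) after superposition.  The transform maps
#'   `moving` as `moving %*% t(rotation) + translation`.
#' @examples
#' set.seed(1)
#' pts <- matrix(rnorm(24), ncol = 3)
#' kabschSuperpose(pts, pts)$rmsd
#' @export
kabschSuperpose <- function(moving, reference) {
    moving <- as.matrix(moving)
    reference <- as.matrix(reference)
    if (!is.numeric(moving) || ncol(moving) != 3L || ncol(reference) != 3L)
        stop("point sets must be n x 3 numeric matrices")
    n <- nrow(moving)
    if (n != nrow(reference)) stop("point sets must have equal sizes")
    if (n < 3L)
        stop("degenerate geometry: need at least 3 points for a unique fit")
    cm <- colMeans(moving)
    cr <- colMeans(reference)
    A <- sweep(moving, 2L, cm)
    B <- sweep(reference, 2L, cr)
    ## collinear configurations leave the rotation about the axis free
    sv <- svd(A, nu = 0, nv = 0)$d
    if (sv[2L] < 1e-8 * max(1, sv[1L]))
        stop("degenerate geometry: moving points are (nearly) collinear")
    H <- crossprod(A, B)               # 3x3 covariance
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    D <- diag(c(1, 1, d))
    R <- s$v %*% D %*% t(s$u)
    t_vec <- cr - as.numeric(R %*% cm)
    fitted <- A %*% t(R)               # centred fit
    rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
    list(rotation = R, translation = t_vec, rmsd = rmsd)
}

.applyTransform <- function(xyz, fit) {
    sweep(as.matrix(xyz) %*% t(fit$rotation), 2L, -fit$translation)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

## Resolve a protein selection (row indices into native protein atoms) to
## paired coordinate matrices through the correspondence.  Returns NULL
## entries where the prediction lacks the atom.
.pairedProteinCoords <- function(native, predicted, corr, nativeRows) {
    idx <- match(nativeRows, corr@proteinPairs$native)
    ok <- !is.na(idx)
    pn <- corr@proteinPairs$native[idx[ok]]
    pp <- corr@proteinPairs$predicted[idx[ok]]
    list(native = as.matrix(proteinAtoms(native)[pn, c("x", "y", "z")]),
         predicted = as.matrix(proteinAtoms(predicted)[pp, c("x", "y", "z")]),
         coverage = mean(ok))
}

.pairedLigandCoords <- function(native, predicted, corr) {
    lp <- corr@ligandPairs
    if (!nrow(lp)) stop("correspondence has no ligand pairs")
    list(native = as.matrix(ligandAtoms(native)[lp$native,
                                                c("x", "y", "z")]),
         predicted = as.matrix(ligandAtoms(predicted)[lp$predicted,
                                                      c("x", "y", "z")]))
}

#' Aligned RMSD over a selection
#'
#' Superposes the predicted structure onto the native one using only the
#' selected (and correspondence-resolvable) atoms, and returns the RMSD over
#' those same atoms.
#'
#' @param native,predicted \linkS4class{PLComplex} objects.
#' @param selection `"backbone"`, `"ligand"`, or a
#'   \linkS4class{PocketSelection}.
#' @param correspondence an \linkS4class{AtomCorrespondence} between the two
#'   complexes (built with [buildCorrespondence()] if omitted).
#' @return RMSD in nm.
#' @export
alignedRMSD <- function(native, predicted, selection,
                        correspondence = NULL) {
    if (is.null(correspondence))
        correspondence <- buildCorrespondence(native, predicted)
    if (is(selection, "PocketSelection")) {
        rows <- .pocketRows(selection, proteinAtoms(native))
        rows <- rows[!is.na(rows)]
        if (!length(rows)) stop("pocket selection resolves to zero atoms")
        pc <- .pairedProteinCoords(native, predicted, correspondence, rows)
        if (!nrow(pc$native))
            stop("pocket selection not resolvable through the correspondence")
        return(kabschSuperpose(pc$predicted, pc$native)$rmsd)
    }
    selection <- match.arg(selection, c("backbone", "ligand"))
    if (selection == "backbone") {
        rows <- which(proteinAtoms(native)$backbone)
        pc <- .pairedProteinCoords(native, predicted, correspondence, rows)
        if (!nrow(pc$native)) stop("no resolvable backbone atoms")
        return(kabschSuperpose(pc$predicted, pc$native)$rmsd)
    }
    lc <- .pairedLigandCoords(native, predicted, correspondence)
    kabschSuperpose(lc$predicted, lc$native)$rmsd
}

#' Pocket-aligned ligand RMSD
#'
#' The pose-placement metric: the predicted complex is superposed onto the
#' native one using the binding-pocket backbone atoms only; that transform
#' is applied to the predicted ligand, and the heavy-atom RMSD between the
#' transformed predicted ligand and the native ligand is returned directly,
#' with no further fitting.  A correct ligand conformation placed wrongly in
#' a perfect pocket therefore still scores poorly.
#'
#' @inheritParams alignedRMSD
#' @param pocket a \linkS4class{PocketSelection} from [definePocket()].
#' @return RMSD in nm.
#' @export
pocketAlignedLigandRMSD <- function(native, predicted, pocket,
                                    correspondence = NULL) {
    if (is.null(correspondence))
        correspondence <- buildCorrespondence(native, predicted)
    rows <- .pocketRows(pocket, proteinAtoms(native))
    rows <- rows[!is.na(rows)]
    if (!length(rows)) stop("empty pocket selection")
    pc <- .pairedProteinCoords(native, predicted, correspondence, rows)
    if (!nrow(pc$native))
        stop("pocket selection not resolvable through the correspondence")
    fit <- kabschSuperpose(pc$predicted, pc$native)
    lc <- .pairedLigandCoords(native, predicted, correspondence)
    .rmsd(.applyTransform(lc$predicted, fit), lc$native)
}

#' Evaluate one predicted pose against its native complex
#'
#' Computes the four alignment-reference RMSDs: protein backbone, protein
#' pocket (backbone atoms within the pocket), ligand (fitted on the ligand
#' itself), and pocket-aligned ligand.
#'
#' @inheritParams pocketAlignedLigandRMSD
#' @param rank pose rank from the producing engine (never re-ranked here).
#' @param methodLabel engine label recorded on the result.
#' @return a \linkS4class{PoseMetrics}
#' @export
evaluatePose <- function(native, predicted, pocket = NULL,
                         correspondence = NULL, rank = 1L,
                         methodLabel = "") {
    if (is.null(pocket)) pocket <- definePocket(native)
    if (!nrow(pocket@atomKeys)) stop("refusing to evaluate an empty pocket")
    if (is.null(correspondence))
        correspondence <- buildCorrespondence(native, predicted)
    rows <- .pocketRows(pocket, proteinAtoms(native))
    pc <- .pairedProteinCoords(native, predicted, correspondence,
                               rows[!is.na(rows)])
    new("PoseMetrics",
        rmsdBackbone = alignedRMSD(native, predicted, "backbone",
                                   correspondence),
        rmsdPocket = alignedRMSD(native, predicted, pocket, correspondence),
        rmsdLigand = alignedRMSD(native, predicted, "ligand",
                                 correspondence),
        rmsdPocketAlignedLigand = pocketAlignedLigandRMSD(
            native, predicted, pocket, correspondence),
        pocketCoverage = pc$coverage,
        rank = as.integer(rank), methodLabel = methodLabel)
}

.metricSlot <- c(backbone = "rmsdBackbone", pocket = "rmsdPocket",
                 ligand = "rmsdLigand", pal = "rmsdPocketAlignedLigand")

#' Best pose under a reference metric
#'
#' Returns the pose minimising the chosen alignment-reference RMSD; ties are
#' broken in favour of the lower (better) engine rank.
#'
#' @param poses list of \linkS4class{PoseMetrics}.
#' @param reference `"backbone"`, `"pocket"`, `"ligand"` or `"pal"`
#'   (pocket-aligned ligand).
#' @return the winning \linkS4class{PoseMetrics}
#' @export
bestOf <- function(poses, reference = c("pal", "ligand", "pocket",
                                        "backbone")) {
    reference <- match.arg(reference)
    if (!length(poses)) stop("empty pose list")
    vals <- vapply(poses, slot, numeric(1), .metricSlot[[reference]])
    ranks <- vapply(poses, slot, integer(1), "rank")
    ord <- order(vals, ranks)
    poses[[ord[1L]]]
}

#' Coerce PoseMetrics to a one-row data.frame
#'
#' @param m a \linkS4class{PoseMetrics}
#' @param entry_id entry identifier for the row.
#' @return one-row data.frame matching the \linkS4class{EvaluationTable}
#'   record schema.
#' @export
poseMetricsRow <- function(m, entry_id = NA_character_) {
    data.frame(entry_id = entry_id, method = m@methodLabel, rank = m@rank,
               rmsd_backbone = m@rmsdBackbone, rmsd_pocket = m@rmsdPocket,
               rmsd_ligand = m@rmsdLigand,
               rmsd_pal = m@rmsdPocketAlignedLigand,
               pocket_coverage = m@pocketCoverage,
               stringsAsFactors = FALSE)
}
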