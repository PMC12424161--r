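#' @include AllClasses.R structure-io.R correspondence.R pose-metrics.R
NULL

.unit <- function(v) v / sqrt(sum(v^2))

.randomUnit <- function() {
    v <- stats::rnorm(3)
    .unit(v)
}

## Rodrigues rotation matrix for `angle` radians about unit `axis`.
.rotationMatrix <- function(axis, angle) {
    a <- .unit(axis)
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Ideal helix curve used for the toy backbone: ~100 deg turn and 0.15 nm
## rise per residue, CA radius 0.23 nm.
.helixPoint <- function(t, radius = 0.23, rise = 0.15,
                        turn = 100 * pi / 180) {
    c(radius * cos(turn * t), radius * sin(turn * t), rise * t)
}

.CC_BOND <- 0.1533   # nm
.CF_BOND <- 0.135
.CO_BOND <- 0.126
.TETRA <- acos(-1 / 3)

## Two tetrahedral directions completing a centre with unit bond vectors
## u1, u2 (exact tetrahedral geometry).
.tetraPair <- function(u1, u2) {
    w1 <- .unit(u1 + u2)
    w2 <- .unit(c(u1[2] * u2[3] - u1[3] * u2[2],
                  u1[3] * u2[1] - u1[1] * u2[3],
                  u1[1] * u2[2] - u1[2] * u2[1]))
    a <- cos(.TETRA / 2)        # 0.57735
    b <- sin(.TETRA / 2)        # 0.81650
    list(-a * w1 + b * w2, -a * w1 - b * w2)
}

.orthobasis <- function(u) {
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- .unit(c(u[2] * ref[3] - u[3] * ref[2],
                  u[3] * ref[1] - u[1] * ref[3],
                  u[1] * ref[2] - u[2] * ref[1]))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    list(e1, e2)
}

## All-anti perfluoroalkyl chain with a carboxylate head: carbon 1 carries
## two oxygens (sp2), carbons 2..n-1 are CF2, carbon n is CF3.  Exact
## tetrahedral fluorine geometry, so graph-symmetric atoms are exactly
## equivalent.
.perfluoroLigand <- function(nCarbons) {
    dz <- .CC_BOND * sin(.TETRA / 2)
    dx <- sqrt(.CC_BOND^2 - dz^2)
    C <- t(vapply(seq_len(nCarbons), function(k)
        c(dx * (k %% 2), 0, dz * k), numeric(3)))
    pos <- list(); el <- character(); nm <- character()
    addAtom <- function(p, e, n) {
        pos[[length(pos) + 1L]] <<- p
        el[length(el) + 1L] <<- e
        nm[length(nm) + 1L] <<- n
    }
    for (k in seq_len(nCarbons)) addAtom(C[k, ], "C", paste0("C", k))
    nF <- 0L
    if (nCarbons >= 3L) for (k in 2:(nCarbons - 1L)) {
        tp <- .tetraPair(.unit(C[k - 1L, ] - C[k, ]),
                         .unit(C[k + 1L, ] - C[k, ]))
        for (d in tp) {
            nF <- nF + 1L
            addAtom(C[k, ] + .CF_BOND * d, "F", paste0("F", nF))
        }
    }
    u <- .unit(C[nCarbons - 1L, ] - C[nCarbons, ])
    e12 <- .orthobasis(u)
    for (m in 0:2) {
        d <- -u / 3 + sqrt(8) / 3 * (cos(2 * pi * m / 3) * e12[[1]] +
                                     sin(2 * pi * m / 3) * e12[[2]])
        nF <- nF + 1L
        addAtom(C[nCarbons, ] + .CF_BOND * d, "F", paste0("F", nF))
    }
    u <- .unit(C[2L, ] - C[1L, ])
    e12 <- .orthobasis(u)
    for (m in 1:2) {
        d <- -0.5 * u + (if (m == 1L) 1 else -1) * (sqrt(3) / 2) * e12[[1]]
        addAtom(C[1L, ] + .CO_BOND * d, "O", paste0("O", m))
    }
    xyz <- do.call(rbind, pos)
    data.frame(serial = seq_along(el), name = nm, element = el,
               resname = "PFA", resno = 1L, chain = "L",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               backbone = FALSE, stringsAsFactors = FALSE)
}

#' Generate a deterministic toy protein-PFAS complex
#'
#' The protein is an ideal poly-alanine alpha-helical backbone (N, CA, C, O
#' heavy atoms per residue; ~100 degrees turn and 0.15 nm rise per
#' residue); the ligand is an all-anti perfluoroalkyl chain with a
#' carboxylate head (CF2 interior, CF3 terminus, exact tetrahedral fluorine
#' geometry), placed alongside the helix with its centroid well inside
#' pocket range of the backbone.  The seed rotates the ligand rigidly about
#' its own axis, so every output is a pure function of `(seed, nResidues,
#' ligandChainLength)`.
#'
#' @param seed integer seed.
#' @param nResidues number of helical residues (>= 20).
#' @param ligandChainLength carbon count of the perfluoroalkyl chain
#'   (>= 2); 8 gives perfluorooctanoate topology (C8 F15 O2).
#' @return a native \linkS4class{PLComplex}
#' @examples
#' cx <- makeToyComplex(seed = 7, ligandChainLength = 8)
#' table(ligandAtoms(cx)$element)
#' @export
makeToyComplex <- function(seed = 1L, nResidues = 30L,
                           ligandChainLength = 8L) {
    if (nResidues < 20L) stop("nResidues must be >= 20")
    if (ligandChainLength < 2L) stop("ligandChainLength must be >= 2")
    n <- as.integer(nResidues)
    rows <- vector("list", n)
    serial <- 0L
    for (i in seq_len(n)) {
        ca <- .helixPoint(i)
        nn <- .helixPoint(i - 0.35)
        cc <- .helixPoint(i + 0.35)
        oo <- cc + 0.123 * .unit(c(cc[1], cc[2], 0))
        at <- rbind(nn, ca, cc, oo)
        rows[[i]] <- data.frame(serial = serial + 1:4,
                                name = c("N", "CA", "C", "O"),
                                element = c("N", "C", "C", "O"),
                                resname = "ALA", resno = i, chain = "A",
                                x = at[, 1], y = at[, 2], z = at[, 3],
                                backbone = TRUE, stringsAsFactors = FALSE)
        serial <- serial + 4L
    }
    prot <- do.call(rbind, rows)
    rownames(prot) <- NULL
    lig <- .perfluoroLigand(as.integer(ligandChainLength))
    lig$serial <- lig$serial + serial
    xyz <- as.matrix(lig[, c("x", "y", "z")])
    cen <- colMeans(xyz)
    .withSeed(seed, {
        R <- .rotationMatrix(c(0, 0, 1), stats::runif(1, 0, 2 * pi))
        xyz <- sweep(sweep(xyz, 2L, cen) %*% t(R), 2L, -cen)
    })
    ## re-centre the ligand beside the helix midpoint
    target <- c(0.55, 0, 0.15 * (n + 1) / 2)
    xyz <- sweep(xyz, 2L, colMeans(xyz) - target)
    lig$x <- xyz[, 1]; lig$y <- xyz[, 2]; lig$z <- xyz[, 3]
    new("PLComplex", entryID = sprintf("TOY%04d", as.integer(seed)),
        ligandID = "PFA", releaseDate = as.Date(NA),
        proteinAtoms = prot, ligandAtoms = lig, sourceFormat = "synthetic")
}

.applyRigid <- function(xyz, R, centre, t_vec) {
    sweep(sweep(xyz, 2L, centre) %*% t(R), 2L, -(centre + t_vec))
}

#' Perturb a native complex into a synthetic "predicted" pose
#'
#' Realises one controlled error mode (see
#' \linkS4class{PerturbationSpec}):
#' \describe{
#'   \item{global_rigid}{rotate the whole complex by `magnitude` degrees
#'     about a random axis through its centroid and translate it by a random
#'     vector of up to 1 nm — all four metrics remain 0.}
#'   \item{ligand_rigid}{translate the ligand only, by exactly `magnitude`
#'     nm in a random direction — the pocket-aligned ligand RMSD equals the
#'     magnitude while the ligand-aligned RMSD stays 0 (an orientation
#'     failure).}
#'   \item{ligand_internal}{rotate a random internal C-C torsion of the
#'     ligand by `magnitude` degrees, leaving bond lengths and angles
#'     untouched (a ligand-structure failure).}
#'   \item{pocket_noise}{add isotropic Gaussian noise with per-coordinate
#'     sigma `magnitude` nm to the pocket backbone atoms (a
#'     pocket-structure failure).}
#'   \item{combined}{ligand translation by `magnitude` nm, a 120-degree
#'     torsion kick, and pocket noise with sigma `magnitude`/2.}
#' }
#'
#' @param native a native \linkS4class{PLComplex}.
#' @param spec a \linkS4class{PerturbationSpec}.
#' @return the perturbed \linkS4class{PLComplex}
#' @export
perturb <- function(native, spec) {
    stopifnot(is(native, "PLComplex"), is(spec, "PerturbationSpec"))
    validObject(spec)
    prot <- proteinAtoms(native)
    lig <- ligandAtoms(native)
    pxyz <- as.matrix(prot[, c("x", "y", "z")])
    lxyz <- as.matrix(lig[, c("x", "y", "z")])
    .withSeed(spec@seed, {
        mag <- spec@magnitude
        if (spec@mode == "global_rigid") {
            cen <- colMeans(rbind(pxyz, lxyz))
            R <- .rotationMatrix(.randomUnit(), mag * pi / 180)
            tv <- stats::runif(1, 0, 1) * .randomUnit()
            pxyz <- .applyRigid(pxyz, R, cen, tv)
            lxyz <- .applyRigid(lxyz, R, cen, tv)
        } else if (spec@mode == "ligand_rigid") {
            lxyz <- sweep(lxyz, 2L, -mag * .randomUnit())
        } else if (spec@mode == "ligand_internal") {
            lxyz <- .torsionKick(lig, lxyz, mag)
        } else if (spec@mode == "pocket_noise") {
            pxyz <- .pocketNoise(native, prot, pxyz, mag)
        } else if (spec@mode == "combined") {
            lxyz <- sweep(lxyz, 2L, -mag * .randomUnit())
            lxyz <- .torsionKick(lig, lxyz, 120)
            pxyz <- .pocketNoise(native, prot, pxyz, mag / 2)
        }
    })
    prot$x <- pxyz[, 1]; prot$y <- pxyz[, 2]; prot$z <- pxyz[, 3]
    lig$x <- lxyz[, 1]; lig$y <- lxyz[, 2]; lig$z <- lxyz[, 3]
    new("PLComplex", entryID = entryID(native), ligandID = ligandID(native),
        releaseDate = releaseDate(native), proteinAtoms = prot,
        ligandAtoms = lig, sourceFormat = "synthetic")
}

## Rotate the smaller side of a random internal C-C bond about the bond
## axis.  Bond lengths/angles are untouched; only the chosen torsion moves.
.torsionKick <- function(lig, lxyz, degrees) {
    bonds <- inferBonds(lig)
    cc <- bonds[lig$element[bonds$i] == "C" & lig$element[bonds$j] == "C", ,
                drop = FALSE]
    if (!nrow(cc)) stop("ligand has no C-C bond to rotate")
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < nrow(lig))
        g <- igraph::add_vertices(g, nrow(lig) - igraph::vcount(g))
    sides <- lapply(seq_len(nrow(cc)), function(k) {
        g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
            g, c(cc$i[k], cc$j[k])))
        comp <- igraph::components(g2)$membership
        side <- which(comp == comp[cc$j[k]])
        list(k = k, side = side)
    })
    ## internal = mid-chain: both endpoint carbons have >= 2 carbon
    ## neighbours, so the kick swings a real chain fragment rather than a
    ## near-symmetric terminal group; fall back to any splitting C-C bond
    nCnb <- vapply(seq_len(nrow(lig)), function(v) {
        nb <- c(bonds$j[bonds$i == v], bonds$i[bonds$j == v])
        sum(lig$element[nb] == "C")
    }, numeric(1))
    internal <- Filter(function(s) {
        n1 <- length(s$side)
        n1 >= 2L && (nrow(lig) - n1) >= 2L &&
            nCnb[cc$i[s$k]] >= 2L && nCnb[cc$j[s$k]] >= 2L
    }, sides)
    if (!length(internal))
        internal <- Filter(function(s) {
            n1 <- length(s$side); n1 >= 2L && (nrow(lig) - n1) >= 2L
        }, sides)
    if (!length(internal)) stop("ligand has no internal C-C bond")
    pick <- internal[[sample.int(length(internal), 1L)]]
    i <- cc$i[pick$k]; j <- cc$j[pick$k]
    axis <- .unit(lxyz[j, ] - lxyz[i, ])
    R <- .rotationMatrix(axis, degrees * pi / 180)
    moving <- setdiff(pick$side, c(i, j))
    lxyz[moving, ] <- .applyRigid(lxyz[moving, , drop = FALSE], R,
                                  lxyz[j, ], c(0, 0, 0))
    lxyz
}

.pocketNoise <- function(native, prot, pxyz, sigma) {
    pocket <- definePocket(native)
    rows <- .pocketRows(pocket, prot)
    rows <- rows[!is.na(rows)]
    pxyz[rows, ] <- pxyz[rows, ] +
        matrix(stats::rnorm(3 * length(rows), sd = sigma), ncol = 3)
    pxyz
}

#' Generate a perturbation cohort of known failure modes
#'
#' Builds one toy native complex and `nSystems` perturbed poses drawn from
#' the mode mixture of the cohort spec, evaluates each pose, and returns
#' the evaluation table together with the true generating modes — the
#' ground truth against which [failureModes()] recovery is judged.
#'
#' Every cohort member is a genuine failure of its designated mode: the
#' perturbation seed is redrawn (deterministically) until the mode's
#' signature metric exceeds the threshold — pocket-aligned ligand RMSD for
#' `ligand_rigid`, ligand-aligned RMSD for `ligand_internal`, pocket RMSD
#' for `pocket_noise` — and the pose fails the pocket-aligned criterion.
#' This conditioning is part of the cohort's definition (a cohort of
#' failures), not of the perturbation operator itself.
#'
#' @param spec a \linkS4class{CohortSpec} with a `modeMixture` over
#'   `ligand_rigid`, `ligand_internal` and `pocket_noise`.
#' @param magnitudes named per-mode magnitudes (0.45 nm translation,
#'   150 degree torsion, 0.9 nm pocket sigma by default).
#' @param threshold failure threshold in nm (default 0.2).
#' @param nResidues,ligandChainLength toy complex parameters; the default
#'   C12 chain gives the torsion mode enough lever arm for decisive
#'   conformational errors.
#' @param maxAttempts seed redraws allowed per system before erroring.
#' @return list with `table` (an \linkS4class{EvaluationTable}) and
#'   `modes` (character vector of true modes per system).
#' @export
makePerturbationCohort <- function(spec,
                                   magnitudes = c(ligand_rigid = 0.45,
                                                  ligand_internal = 150,
                                                  pocket_noise = 0.9),
                                   threshold = 0.2,
                                   nResidues = 24L,
                                   ligandChainLength = 12L,
                                   maxAttempts = 100L) {
    stopifnot(is(spec, "CohortSpec"), length(spec@modeMixture) > 0L)
    native <- makeToyComplex(seed = spec@seed, nResidues = nResidues,
                             ligandChainLength = ligandChainLength)
    corr <- buildCorrespondence(native, native)
    pocket <- definePocket(native)
    ## stratified realisation of the mixture: counts are fixed at their
    ## expectations (largest-remainder rounding), order shuffled — the
    ## cohort then carries the stated mixture exactly, so recovery error
    ## reflects the classifier alone
    raw <- spec@modeMixture * spec@nSystems
    cnt <- floor(raw)
    rem <- spec@nSystems - sum(cnt)
    if (rem > 0) {
        ord <- order(raw - cnt, decreasing = TRUE)
        cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
    }
    modes <- .withSeed(spec@seed,
                       sample(rep(names(spec@modeMixture), times = cnt)))
    subSeeds <- .withSeed(spec@seed + 1L,
                          sample.int(2L^20L, spec@nSystems))
    signature <- c(ligand_rigid = "rmsdPocketAlignedLigand",
                   ligand_internal = "rmsdLigand",
                   pocket_noise = "rmsdPocket")
    rows <- vector("list", spec@nSystems)
    for (s in seq_len(spec@nSystems)) {
        mode <- modes[s]
        m <- NULL
        for (attempt in seq_len(maxAttempts)) {
            ps <- perturbationSpec(mode, magnitudes[[mode]],
                                   seed = subSeeds[s] * maxAttempts +
                                       attempt)
            pred <- perturb(native, ps)
            cand <- evaluatePose(native, pred, pocket, corr, rank = 1L,
                                 methodLabel = "synthetic")
            if (slot(cand, signature[[mode]]) > threshold &&
                cand@rmsdPocketAlignedLigand > threshold) {
                m <- cand
                break
            }
        }
        if (is.null(m))
            stop("could not realise a ", mode, " failure in ", maxAttempts,
                 " attempts; increase the magnitude")
        rows[[s]] <- poseMetricsRow(m, sprintf("SYS%04d", s))
    }
    df <- do.call(rbind, rows)
    df$true_mode <- modes
    list(table = EvaluationTable(df), modes = modes)
}

#' Generate a synthetic evaluation table with known success rates
#'
#' Draws per-system top-`nRanks` pocket-aligned ligand RMSDs so that each
#' pose independently succeeds (RMSD <= threshold) with the split's success
#' probability; the rank-1 (Best pose) success rate therefore recovers the
#' specified probability.  The protein backbone, pocket and ligand
#' references are drawn at fixed high success probabilities (0.80, 0.93,
#' 0.92) typical of structure predictors, and each system gets a PFAS
#' charge category from a fixed multinomial (60/30/10
#' negative/neutral/positive).
#'
#' @param spec a \linkS4class{CohortSpec}; `nSystems` systems are generated
#'   per split named in `successProb`.
#' @param method method label for the generated records.
#' @param nRanks poses per system (default 5).
#' @param threshold success threshold in nm (default 0.2).
#' @return an \linkS4class{EvaluationTable} with `split` and
#'   `charge_category` columns.
#' @export
makeEvaluationTable <- function(spec, method = "AF3", nRanks = 5L,
                                threshold = 0.2) {
    stopifnot(is(spec, "CohortSpec"))
    drawRef <- function(n, p) {
        hit <- stats::runif(n) < p
        ifelse(hit, stats::runif(n, 0.1 * threshold, threshold),
               stats::runif(n, threshold * 1.05, threshold * 6))
    }
    .withSeed(spec@seed, {
        rows <- list()
        for (s in names(spec@successProb)) {
            p <- spec@successProb[[s]]
            for (e in seq_len(spec@nSystems)) {
                id <- sprintf("SYN_%s_%05d", s, e)
                cc <- sample(c("negative", "neutral", "positive"), 1L,
                             prob = c(0.6, 0.3, 0.1))
                rows[[length(rows) + 1L]] <- data.frame(
                    entry_id = id, method = method, rank = seq_len(nRanks),
                    rmsd_backbone = drawRef(nRanks, 0.80),
                    rmsd_pocket = drawRef(nRanks, 0.93),
                    rmsd_ligand = drawRef(nRanks, 0.92),
                    rmsd_pal = drawRef(nRanks, p),
                    split = s, charge_category = cc,
                    stringsAsFactors = FALSE)
            }
        }
        EvaluationTable(do.call(rbind, rows))
    })
}
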