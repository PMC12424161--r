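# Independent oracles and fixture builders shared across the suite.

# Horn's quaternion-eigenvalue superposition: an implementation of optimal
# rigid superposition independent of the SVD route used by the package.
quatSuperposeRMSD <- function(moving, reference) {
    A <- sweep(moving, 2, colMeans(moving))
    B <- sweep(reference, 2, colMeans(reference))
    M <- crossprod(A, B)
    Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
    Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
    Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
    K <- matrix(c(
        Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
        Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
        Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
        Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
        4, 4, byrow = TRUE)
    lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
    sqrt(max(0, msd))
}

randomRotation <- function() {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

# Apply one rigid motion to every atom of a complex.
transformComplex <- function(cx, R, t) {
    move <- function(df) {
        xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
        df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]
        df$z <- xyz[, 3] + t[3]
        df
    }
    cx@proteinAtoms <- move(cx@proteinAtoms)
    cx@ligandAtoms <- move(cx@ligandAtoms)
    cx
}

ligandXYZ <- function(cx) as.matrix(ligandAtoms(cx)[, c("x", "y", "z")])

setLigandXYZ <- function(cx, xyz) {
    cx@ligandAtoms$x <- xyz[, 1]
    cx@ligandAtoms$y <- xyz[, 2]
    cx@ligandAtoms$z <- xyz[, 3]
    cx
}

# Minimal hand-built complex: protein backbone atoms at given coordinates
# (one residue of four atoms per row group), ligand atoms at given
# coordinates.
miniComplex <- function(proteinXYZ, ligandXYZ, ligandElements = NULL) {
    np <- nrow(proteinXYZ)
    names4 <- rep(c("N", "CA", "C", "O"), length.out = np)
    prot <- data.frame(serial = seq_len(np), name = names4,
                       element = ifelse(names4 == "N", "N",
                                        ifelse(names4 == "O", "O", "C")),
                       resname = "ALA",
                       resno = rep(seq_len(ceiling(np / 4)),
                                   each = 4)[seq_len(np)],
                       chain = "A",
                       x = proteinXYZ[, 1], y = proteinXYZ[, 2],
                       z = proteinXYZ[, 3],
                       backbone = TRUE, stringsAsFactors = FALSE)
    nl <- nrow(ligandXYZ)
    if (is.null(ligandElements)) ligandElements <- rep("C", nl)
    lig <- data.frame(serial = np + seq_len(nl),
                      name = paste0(ligandElements, seq_len(nl)),
                      element = ligandElements, resname = "LIG",
                      resno = 1L, chain = "L",
                      x = ligandXYZ[, 1], y = ligandXYZ[, 2],
                      z = ligandXYZ[, 3],
                      backbone = FALSE, stringsAsFactors = FALSE)
    new("PLComplex", entryID = "MINI", ligandID = "LIG",
        releaseDate = as.Date(NA), proteinAtoms = prot, ligandAtoms = lig,
        sourceFormat = "synthetic")
}

# Random chemically plausible fluorocarbon tree: carbons form a random
# tree, remaining valences filled with F or H at random.
randomFluorocarbon <- function(nC, pF = 0.7) {
    stopifnot(nC >= 1)
    deg <- rep(0L, nC)
    edges <- list()
    for (k in seq_len(nC)[-1]) {
        open <- which(deg[seq_len(k - 1L)] < 4L)
        parent <- open[sample.int(length(open), 1L)]
        edges[[k - 1L]] <- c(k, parent)
        deg[k] <- deg[k] + 1L
        deg[parent] <- deg[parent] + 1L
    }
    bonds <- if (length(edges)) {
        em <- do.call(rbind, edges)
        data.frame(i = em[, 1], j = em[, 2], order = 1)
    } else data.frame(i = integer(), j = integer(), order = numeric())
    el <- rep("C", nC)
    extra <- list()
    nxt <- nC
    for (c_idx in seq_len(nC)) {
        for (slot in seq_len(4 - deg[c_idx])) {
            nxt <- nxt + 1L
            el[nxt] <- if (runif(1) < pF) "F" else "H"
            extra[[length(extra) + 1L]] <-
                data.frame(i = c_idx, j = nxt, order = 1)
        }
    }
    bonds <- rbind(bonds, do.call(rbind, extra))
    moleculeGraph(el, bonds, name = "fuzz")
}

# Two-method synthetic evaluation table with shared entry ids.
twoMethodTable <- function(n = 40, seed = 1,
                           pA = c(Before = 0.7, After = 0.5),
                           pB = c(Before = 0.5, After = 0.45)) {
    ta <- records(makeEvaluationTable(cohortSpec(n, pA, seed = seed),
                                      method = "A"))
    tb <- records(makeEvaluationTable(cohortSpec(n, pB, seed = seed + 500),
                                      method = "B"))
    EvaluationTable(rbind(ta, tb))
}
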