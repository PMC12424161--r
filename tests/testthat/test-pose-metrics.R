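test_that("Kabsch superposition recovers rigid motions exactly", {
    set.seed(1)
    pts <- matrix(rnorm(30), ncol = 3)
    fit0 <- kabschSuperpose(pts, pts)
    expect_lt(fit0$rmsd, 1e-12)
    expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
    expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-10)
    # rotate 37 degrees about a random axis + translate
    axis <- c(1, 2, 3) / sqrt(14)
    th <- 37 * pi / 180
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    moved <- pts %*% t(R) + matrix(c(0.4, -0.2, 1.1), nrow(pts), 3,
                                   byrow = TRUE)
    fit <- kabschSuperpose(moved, pts)
    expect_lt(fit$rmsd, 1e-10)
    mapped <- sweep(moved %*% t(fit$rotation), 2, -fit$translation)
    expect_lt(max(abs(mapped - pts)), 1e-10)
})

test_that("Kabsch agrees with an independent quaternion oracle", {
    set.seed(2)
    for (k in 1:50) {
        a <- matrix(rnorm(24), ncol = 3)
        b <- matrix(rnorm(24), ncol = 3)
        expect_equal(kabschSuperpose(a, b)$rmsd, quatSuperposeRMSD(a, b),
                     tolerance = 1e-8)
    }
})

test_that("degenerate geometries are refused", {
    expect_error(kabschSuperpose(matrix(rnorm(6), ncol = 3),
                                 matrix(rnorm(6), ncol = 3)),
                 "at least 3")
    line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
    expect_error(kabschSuperpose(line, line + 1), "collinear")
})

test_that("reflections are never returned as rotations", {
    set.seed(3)
    for (k in 1:20) {
        a <- matrix(rnorm(12), ncol = 3)
        b <- -a + matrix(rnorm(12, sd = 0.1), ncol = 3)  # near-reflection
        fit <- kabschSuperpose(a, b)
        expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
        expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-10)
    }
})

test_that("aligned RMSD matches the noise expectation on a large
           selection", {
    cx <- makeToyComplex(seed = 20, nResidues = 50)  # 200 backbone atoms
    sigma <- 0.05
    vals <- vapply(1:20, function(s) {
        set.seed(s)
        pred <- cx
        n <- nrow(pred@proteinAtoms)
        pred@proteinAtoms$x <- pred@proteinAtoms$x + rnorm(n, sd = sigma)
        pred@proteinAtoms$y <- pred@proteinAtoms$y + rnorm(n, sd = sigma)
        pred@proteinAtoms$z <- pred@proteinAtoms$z + rnorm(n, sd = sigma)
        alignedRMSD(cx, pred, "backbone")
    }, numeric(1))
    expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.1)
})

test_that("scaling a 3-atom selection gives the closed-form RMSD", {
    tri <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0))
    scaled <- 1.1 * tri
    # optimal rotation is the identity; residual is 0.1 x rms distance
    # of the vertices from their centroid
    cen <- colMeans(tri)
    expected <- 0.1 * sqrt(mean(rowSums(sweep(tri, 2, cen)^2)))
    expect_equal(kabschSuperpose(scaled, tri)$rmsd, expected,
                 tolerance = 1e-10)
    expect_equal(expected, 0.02, tolerance = 1e-12)
    # same number through the aligned-RMSD route with a 3-atom pocket
    nat <- miniComplex(tri, rbind(c(0.1, 0.1, 0)))
    prd <- miniComplex(scaled, rbind(c(0.1, 0.1, 0)))
    pocket <- new("PocketSelection",
                  atomKeys = proteinAtoms(nat)[, c("chain", "resno",
                                                   "name")],
                  cutoff = 1, centroid = c(0.1, 0.1, 0))
    corr <- buildCorrespondence(nat, prd)
    expect_equal(alignedRMSD(nat, prd, pocket, corr), 0.02,
                 tolerance = 1e-10)
})

test_that("pocket-aligned ligand RMSD isolates placement error", {
    cx <- makeToyComplex(seed = 21)
    pocket <- definePocket(cx)
    corr <- buildCorrespondence(cx, cx)
    # global rigid motion: all metrics vanish
    set.seed(7)
    moved <- transformComplex(cx, randomRotation(), rnorm(3))
    m <- evaluatePose(cx, moved, pocket, corr)
    for (v in c(m@rmsdBackbone, m@rmsdPocket, m@rmsdLigand,
                m@rmsdPocketAlignedLigand))
        expect_lt(v, 1e-9)
    # pure ligand translation: pal equals the distance, ligand fit is 0
    t <- c(0.3, 0, 0)
    pred <- setLigandXYZ(cx, sweep(ligandXYZ(cx), 2, -t))
    expect_lt(alignedRMSD(cx, pred, "ligand", corr), 1e-12)
    expect_equal(pocketAlignedLigandRMSD(cx, pred, pocket, corr), 0.3,
                 tolerance = 1e-12)
})

test_that("in-place ligand rotation matches direct enumeration", {
    cx <- makeToyComplex(seed = 22)
    pocket <- definePocket(cx)
    corr <- buildCorrespondence(cx, cx)
    xyz <- ligandXYZ(cx)
    cen <- colMeans(xyz)
    R <- diag(c(-1, -1, 1))                      # 180 deg about z
    rot <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, -cen)
    pred <- setLigandXYZ(cx, rot)
    expect_lt(alignedRMSD(cx, pred, "ligand", corr), 1e-9)
    direct <- sqrt(mean(rowSums((rot - xyz)^2)))  # enumeration oracle
    expect_equal(pocketAlignedLigandRMSD(cx, pred, pocket, corr), direct,
                 tolerance = 1e-10)
    expect_gt(direct, 0.05)
})

test_that("each error mode moves only its own metric", {
    cx <- makeToyComplex(seed = 23)
    pocket <- definePocket(cx)
    corr <- buildCorrespondence(cx, cx)
    lr <- evaluatePose(cx, perturb(cx, perturbationSpec("ligand_rigid",
                                                        0.25, seed = 2)),
                       pocket, corr)
    expect_lt(lr@rmsdLigand, 1e-9)
    expect_lt(lr@rmsdBackbone, 1e-9)
    expect_equal(lr@rmsdPocketAlignedLigand, 0.25, tolerance = 1e-9)
    pn <- evaluatePose(cx, perturb(cx, perturbationSpec("pocket_noise",
                                                        0.05, seed = 3)),
                       pocket, corr)
    expect_gt(pn@rmsdPocket, 0)
    expect_lt(pn@rmsdLigand, 1e-12)
})

test_that("all four metrics are invariant under rigid pre-motions", {
    cx <- makeToyComplex(seed = 24)
    pocket <- definePocket(cx)
    corr <- buildCorrespondence(cx, cx)
    pred <- perturb(cx, perturbationSpec("combined", 0.3, seed = 5))
    ref <- evaluatePose(cx, pred, pocket, corr)
    set.seed(31)
    for (k in 1:5) {
        cx2 <- transformComplex(cx, randomRotation(), rnorm(3))
        pred2 <- transformComplex(pred, randomRotation(), rnorm(3))
        m <- evaluatePose(cx2, pred2, definePocket(cx2), corr)
        expect_equal(m@rmsdBackbone, ref@rmsdBackbone, tolerance = 1e-9)
        expect_equal(m@rmsdPocket, ref@rmsdPocket, tolerance = 1e-9)
        expect_equal(m@rmsdLigand, ref@rmsdLigand, tolerance = 1e-9)
        expect_equal(m@rmsdPocketAlignedLigand,
                     ref@rmsdPocketAlignedLigand, tolerance = 1e-9)
    }
})

test_that("the fitted ligand metric never exceeds the fit-free one for
           rigid ligand perturbations", {
    cx <- makeToyComplex(seed = 25)
    pocket <- definePocket(cx)
    corr <- buildCorrespondence(cx, cx)
    for (s in 1:10) {
        pred <- perturb(cx, perturbationSpec("ligand_rigid",
                                             runif(1, 0.05, 0.5),
                                             seed = s))
        m <- evaluatePose(cx, pred, pocket, corr)
        expect_lte(m@rmsdLigand, m@rmsdPocketAlignedLigand + 1e-12)
    }
})

test_that("bestOf minimises the chosen reference and breaks ties by rank", {
    mk <- function(pal, rank)
        new("PoseMetrics", rmsdBackbone = 0.1, rmsdPocket = 0.1,
            rmsdLigand = 0.1, rmsdPocketAlignedLigand = pal,
            pocketCoverage = 1, rank = as.integer(rank), methodLabel = "m")
    poses <- list(mk(0.3, 1), mk(0.1, 2), mk(0.5, 3))
    expect_identical(bestOf(poses, "pal")@rank, 2L)
    expect_identical(bestOf(poses[2], "pal")@rank, 2L)
    tie <- list(mk(0.2, 4), mk(0.2, 2))
    expect_identical(bestOf(tie, "pal")@rank, 2L)
    expect_error(bestOf(list(), "pal"), "empty")
})
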