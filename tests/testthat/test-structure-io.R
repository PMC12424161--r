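test_that("coordinates are converted from Angstrom to nm on read", {
    f <- tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
        "ATOM      2  CA  ALA A   2       4.000   5.000   6.000  1.00  0.00           C",
        "ATOM      3  CA  ALA A   3       7.000   8.000   9.000  1.00  0.00           C",
        "HETATM    4  C1  LIG A  10       1.000   0.000   0.000  1.00  0.00           C",
        "HETATM    5  F1  LIG A  10       2.000   0.000   0.000  1.00  0.00           F",
        "END"), f)
    cx <- readComplex(f)
    expect_equal(proteinAtoms(cx)$x[1], 0.100, tolerance = 1e-12)
    expect_equal(ligandAtoms(cx)$x, c(0.1, 0.2), tolerance = 1e-12)
    expect_false(any(proteinAtoms(cx)$element == "H"))
})

test_that("write/read round trips preserve atoms within format precision", {
    cx <- makeToyComplex(seed = 4, nResidues = 22)
    for (fmt in c("pdb", "cif")) {
        f <- tempfile(fileext = paste0(".", fmt))
        writeComplex(cx, f, fmt)
        back <- suppressWarnings(readComplex(f))
        expect_identical(nrow(proteinAtoms(back)), nrow(proteinAtoms(cx)))
        expect_identical(proteinAtoms(back)$name, proteinAtoms(cx)$name)
        expect_identical(ligandAtoms(back)$name, ligandAtoms(cx)$name)
        for (col in c("x", "y", "z")) {
            expect_lt(max(abs(proteinAtoms(back)[[col]] -
                              proteinAtoms(cx)[[col]])), 1e-4)
            expect_lt(max(abs(ligandAtoms(back)[[col]] -
                              ligandAtoms(cx)[[col]])), 1e-4)
        }
    }
})

test_that("gzipped structure files are read transparently", {
    cx <- makeToyComplex(seed = 5)
    f <- tempfile(fileext = ".pdb")
    writeComplex(cx, f)
    fgz <- paste0(f, ".gz")
    con <- gzfile(fgz, "w")
    writeLines(readLines(f), con)
    close(con)
    back <- readComplex(fgz)
    expect_identical(nrow(proteinAtoms(back)), nrow(proteinAtoms(cx)))
    expect_lt(max(abs(ligandAtoms(back)$x - ligandAtoms(cx)$x)), 1e-4)
})

test_that("waters, ions and hydrogens are stripped during cleaning", {
    cx <- makeToyComplex(seed = 6)
    f <- tempfile(fileext = ".pdb")
    writeComplex(cx, f)
    lines <- readLines(f)
    end <- grep("^END", lines)[1]
    waters <- sprintf(
        "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
        2000 + 1:30, 500 + 1:30, runif(30, 0, 40), runif(30, 0, 40),
        runif(30, 0, 40))
    ion <- "HETATM 2100 NA    NA A 600      10.000  10.000  10.000  1.00  0.00          NA"
    hyd <- "HETATM 2101  H1  PFA L   1       5.500   0.000  23.000  1.00  0.00           H"
    writeLines(c(lines[seq_len(end - 1)], waters, ion, hyd, "END"), f)
    back <- readComplex(f)
    expect_false(any(toupper(ligandAtoms(back)$resname) %in%
                     c("HOH", "WAT", "NA")))
    expect_identical(nrow(ligandAtoms(back)), nrow(ligandAtoms(cx)))
    expect_false(any(ligandAtoms(back)$element == "H"))
})

test_that("several ligand copies need a selector in strict mode", {
    cx <- makeToyComplex(seed = 7)
    f <- tempfile(fileext = ".pdb")
    writeComplex(cx, f)
    lines <- readLines(f)
    end <- grep("^END", lines)[1]
    second <- sprintf(
        "HETATM%5d %-4s LG2 L   2    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        3000 + 1:3, c("C1", "C2", "O1"), c(30, 31, 32), c(0, 0, 0),
        c(0, 0, 0), c("C", "C", "O"))
    writeLines(c(lines[seq_len(end - 1)], second, "END"), f)
    expect_error(readComplex(f), "ligand copies")
    got <- readComplex(f, ligand = "LG2")
    expect_identical(ligandID(got), "LG2")
    first <- readComplex(f, strict = FALSE)
    expect_identical(ligandID(first), "PFA")
    expect_error(readComplex(f, ligand = "ZZZ"), "no ligand")
})

test_that("a complex without protein or ligand atoms is invalid", {
    cx <- makeToyComplex(seed = 1)
    expect_error(new("PLComplex", entryID = "X", ligandID = "L",
                     releaseDate = as.Date(NA),
                     proteinAtoms = proteinAtoms(cx)[0, ],
                     ligandAtoms = ligandAtoms(cx),
                     sourceFormat = "synthetic"),
                 "protein")
    expect_error(new("PLComplex", entryID = "X", ligandID = "L",
                     releaseDate = as.Date(NA),
                     proteinAtoms = proteinAtoms(cx),
                     ligandAtoms = ligandAtoms(cx)[0, ],
                     sourceFormat = "synthetic"),
                 "ligand")
})

test_that("very large complexes survive the PDB serial wrap", {
    nres <- 26000L                       # 104000 backbone atoms
    i <- seq_len(nres)
    base <- data.frame(serial = i, name = "CA", element = "C",
                       resname = "ALA", resno = i, chain = "A",
                       x = (i %% 97) / 10, y = (i %% 89) / 10,
                       z = i / 1000, backbone = TRUE,
                       stringsAsFactors = FALSE)
    prot <- do.call(rbind, list(base))
    lig <- ligandAtoms(makeToyComplex(seed = 1))
    big <- new("PLComplex", entryID = "BIG", ligandID = "PFA",
               releaseDate = as.Date(NA), proteinAtoms = prot,
               ligandAtoms = lig, sourceFormat = "synthetic")
    f <- tempfile(fileext = ".pdb")
    writeComplex(big, f)
    back <- readComplex(f)
    expect_identical(nrow(proteinAtoms(back)), nres)
    expect_lt(max(abs(proteinAtoms(back)$x - prot$x)), 1e-4)
})

test_that("pocket selection follows the inclusive distance rule", {
    prot <- rbind(c(0.5, 0, 0), c(1.0, 0, 0), c(1.5, 0, 0), c(0, 0.3, 0))
    lig <- rbind(c(0, 0, 0))
    cx <- miniComplex(prot, lig)
    pk <- definePocket(cx, cutoff = 1.0)
    expect_equal(pocketCentroid(pk), c(0, 0, 0))
    sel <- pocketAtomKeys(pk)
    d <- sqrt(rowSums(prot^2))
    expect_setequal(paste(sel$resno, sel$name),
                    paste(proteinAtoms(cx)$resno,
                          proteinAtoms(cx)$name)[d <= 1.0])
    expect_identical(nrow(sel), 3L)      # the 1.0 nm atom is included
})

test_that("pocket matches a brute-force scan, nests with cutoff, and is
           rigid-invariant", {
    cx <- makeToyComplex(seed = 8)
    prot <- proteinAtoms(cx)
    cen <- colMeans(ligandXYZ(cx))
    d <- sqrt(colSums((t(as.matrix(prot[, c("x", "y", "z")])) - cen)^2))
    for (cutoff in c(0.6, 1.0, 1.4)) {
        pk <- definePocket(cx, cutoff)
        brute <- prot[prot$backbone & d <= cutoff, c("chain", "resno",
                                                     "name")]
        expect_setequal(do.call(paste, pocketAtomKeys(pk)),
                        do.call(paste, brute))
    }
    small <- do.call(paste, pocketAtomKeys(definePocket(cx, 0.7)))
    large <- do.call(paste, pocketAtomKeys(definePocket(cx, 1.1)))
    expect_true(all(small %in% large))
    set.seed(42)
    moved <- transformComplex(cx, randomRotation(), rnorm(3))
    expect_setequal(do.call(paste, pocketAtomKeys(definePocket(moved))),
                    do.call(paste, pocketAtomKeys(definePocket(cx))))
})

test_that("ligand-only PDBQT poses graft onto the native protein", {
    cx <- makeToyComplex(seed = 9)
    lig <- ligandAtoms(cx)
    shift <- 0.25
    qt <- c("MODEL 1", "ROOT",
            sprintf(
                "HETATM%5d %-4s PFA L   1    %8.3f%8.3f%8.3f  0.00  0.00    +0.000 %-2s",
                seq_len(nrow(lig)), lig$name, lig$x * 10 + shift * 10,
                lig$y * 10, lig$z * 10,
                ifelse(lig$element == "F", "F",
                       ifelse(lig$element == "O", "OA", "C"))),
            "ENDROOT", "ENDMDL",
            "MODEL 2",
            "HETATM    1  C1  PFA L   1      99.000  99.000  99.000  0.00  0.00    +0.000 C",
            "ENDMDL")
    f <- tempfile(fileext = ".pdbqt")
    writeLines(qt, f)
    pose <- readLigandPose(cx, f)
    expect_identical(nrow(proteinAtoms(pose)), nrow(proteinAtoms(cx)))
    expect_identical(ligandAtoms(pose)$element, lig$element)
    # only model 1 kept, coordinates shifted by 0.25 nm in x
    expect_equal(ligandAtoms(pose)$x, lig$x + shift, tolerance = 1e-3)
    m <- evaluatePose(cx, pose)
    expect_equal(m@rmsdPocketAlignedLigand, shift, tolerance = 1e-3)
})
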