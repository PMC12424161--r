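test_that("success rate uses an inclusive threshold", {
    expect_equal(successRate(c(0.1, 0.3))$rate, 50)
    expect_equal(successRate(0.2)$rate, 100)          # boundary included
    expect_equal(successRate(c(0.2000001))$rate, 0)
    expect_error(successRate(numeric(0)), "empty")
    # non-decreasing in the threshold
    set.seed(9)
    v <- runif(50, 0, 0.6)
    rates <- vapply(seq(0.05, 0.5, by = 0.05),
                    function(th) successRate(v, th)$rate, numeric(1))
    expect_true(all(diff(rates) >= 0))
})

test_that("bootstrap CIs are deterministic and degenerate correctly", {
    expect_equal(bootstrapCI(rep(1, 25)), c(100, 100))
    expect_equal(bootstrapCI(rep(0, 25)), c(0, 0))
    x <- rbinom(80, 1, 0.6)
    expect_identical(bootstrapCI(x, seed = 11), bootstrapCI(x, seed = 11))
})

test_that("the binomial fast path agrees with explicit index resampling", {
    set.seed(10)
    x <- rbinom(200, 1, 0.65)
    fast <- bootstrapCI(x, nResamples = 6000, seed = 21)
    # independent oracle: literal resampling of the outcome vector
    set.seed(22)
    means <- vapply(seq_len(6000), function(i)
        mean(x[sample.int(200, 200, replace = TRUE)]), numeric(1))
    slow <- 100 * quantile(means, c(0.025, 0.975), names = FALSE)
    expect_lt(max(abs(fast - slow)), 2.5)   # percentage points
})

test_that("bootstrapCI leaves the caller's RNG stream untouched", {
    set.seed(33)
    a1 <- runif(1)
    set.seed(33)
    invisible(bootstrapCI(c(0, 1, 1, 0, 1), seed = 5))
    a2 <- runif(1)
    expect_identical(a1, a2)
})

test_that("Welch test matches the closed-form computation", {
    a <- c(1, 2, 3, 4)
    b <- c(2, 3, 4, 5, 6, 7)
    wt <- welchTest(a, b)
    se2 <- var(a) / length(a) + var(b) / length(b)
    t_hand <- (mean(a) - mean(b)) / sqrt(se2)
    df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 6)^2 / 5)
    p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
    expect_equal(wt$t, t_hand, tolerance = 1e-12)
    expect_equal(wt$df, df_hand, tolerance = 1e-12)
    expect_equal(wt$p, p_hand, tolerance = 1e-12)
    # identical samples: t = 0, p = 1, no stars
    eq <- welchTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(eq$t, 0)
    expect_equal(eq$p, 1)
    expect_identical(eq$stars, "")
    expect_error(welchTest(rep(1, 5), rep(1, 5)), "degenerate")
    expect_error(welchTest(1, c(1, 2)), "at least 2")
})

test_that("significance stars follow the conventional thresholds", {
    set.seed(12)
    big_a <- rnorm(200, 0); big_b <- rnorm(200, 1)
    expect_identical(welchTest(big_a, big_b)$stars, "***")
    expect_identical(welchTest(c(1, 2, 3, 4), c(2, 3, 4, 5, 6, 7))$stars,
                     "")
    # p just under 0.01 gets two stars
    a <- c(0, 0, 1, 1, 1, 0, 0, 0, 1, 0)
    mid <- welchTest(seq(1, 2, length.out = 20),
                     seq(1.35, 2.35, length.out = 20))
    expect_true(mid$stars %in% c("**", "***"))
})

test_that("top-N success matches direct enumeration and clamps n", {
    df <- data.frame(entry_id = rep(c("A", "B"), each = 2),
                     method = "M", rank = c(1L, 2L, 1L, 2L),
                     rmsd_backbone = 0.1, rmsd_pocket = 0.1,
                     rmsd_ligand = 0.1,
                     rmsd_pal = c(0.5, 0.15, 0.3, 0.4))
    tab <- EvaluationTable(df)
    expect_equal(topnSuccess(tab, 1, ci = FALSE)$rate, 0)
    expect_equal(topnSuccess(tab, 2, ci = FALSE)$rate, 50)
    expect_equal(topnSuccess(tab, 99, ci = FALSE)$rate, 50)  # clamped
    # enumeration oracle on a random table
    big <- makeEvaluationTable(cohortSpec(60, c(Only = 0.6), seed = 14))
    rec <- records(big)
    for (n in c(1, 3, 5)) {
        oracle <- vapply(split(rec, rec$entry_id), function(d)
            min(d$rmsd_pal[d$rank <= n]) <= 0.2, logical(1))
        expect_equal(topnSuccess(big, n, ci = FALSE)$rate,
                     100 * mean(oracle))
    }
})

test_that("hybrid success is the union minimum and dominates both
           constituents", {
    tab <- twoMethodTable(n = 50, seed = 15)
    rec <- records(tab)
    hy <- hybridSuccess(tab, c("A", "B"), n = 5, ci = FALSE)
    sa <- topnSuccess(tab, 5, method = "A", ci = FALSE)
    sb <- topnSuccess(tab, 5, method = "B", ci = FALSE)
    expect_gte(hy$rate, max(sa$rate, sb$rate))
    # enumeration oracle
    oracle <- vapply(split(rec, rec$entry_id), function(d)
        min(d$rmsd_pal[d$rank <= 5]) <= 0.2, logical(1))
    expect_equal(hy$rate, 100 * mean(oracle))
    # entries missing one method are excluded with a warning
    rec_b <- rec[!(rec$method == "B" &
                   rec$entry_id == rec$entry_id[1]), ]
    expect_warning(hy2 <- hybridSuccess(EvaluationTable(rec_b),
                                        c("A", "B"), n = 5, ci = FALSE),
                   "excluded")
    expect_identical(hy2$n, length(unique(rec_b$entry_id)) - 1L)
})

test_that("failure classification follows the residual-orientation rule", {
    row <- function(lig, poc, pal)
        data.frame(rmsd_ligand = lig, rmsd_pocket = poc, rmsd_pal = pal)
    expect_null(classifyFailure(row(0.5, 0.5, 0.15)))
    f1 <- classifyFailure(row(0.05, 0.05, 0.45))
    expect_true(f1[["orientation"]])
    expect_false(f1[["ligand_structure"]] || f1[["pocket_structure"]])
    f2 <- classifyFailure(row(0.35, 0.05, 0.50))
    expect_true(f2[["ligand_structure"]])
    expect_false(f2[["orientation"]] || f2[["both"]])
    f3 <- classifyFailure(row(0.30, 0.30, 0.60))
    expect_true(all(f3[c("ligand_structure", "pocket_structure", "both")]))
    expect_false(f3[["orientation"]])
})

test_that("every failure carries a mode and orientation excludes the
           others", {
    tab <- makeEvaluationTable(cohortSpec(150, c(Only = 0.5), seed = 16))
    rec <- records(tab)
    rec1 <- rec[rec$rank == 1, ]
    for (i in seq_len(nrow(rec1))) {
        fl <- classifyFailure(rec1[i, ])
        if (is.null(fl)) next
        expect_true(any(fl[c("orientation", "ligand_structure",
                             "pocket_structure")]))
        if (fl[["orientation"]])
            expect_false(fl[["ligand_structure"]] ||
                         fl[["pocket_structure"]])
        expect_identical(fl[["both"]],
                         fl[["ligand_structure"]] &&
                         fl[["pocket_structure"]])
    }
})

test_that("aggregate reports cover groups, strategies and comparisons", {
    one <- EvaluationTable(data.frame(
        entry_id = "A", method = "M", rank = 1L, rmsd_backbone = 0.1,
        rmsd_pocket = 0.1, rmsd_ligand = 0.1, rmsd_pal = 0.1))
    rep1 <- aggregateReport(one, nResamples = 100, references = "pal")
    expect_true(all(rep1$summary$rate %in% c(0, 100)))
    tab <- makeEvaluationTable(cohortSpec(120, seed = 17))
    grp <- aggregateReport(tab, groupBy = "charge_category",
                           references = "pal", nResamples = 100)
    best <- grp$summary[grp$summary$strategy == "Best", ]
    expect_identical(sum(best$n), 2L * 120L)  # group sizes sum to total
    expect_true(all(c("group", "split") %in% names(grp$summary)))
    expect_true(nrow(grp$comparisons) >= 1)
    expect_true(all(grp$comparisons$p >= 0 & grp$comparisons$p <= 1))
})
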