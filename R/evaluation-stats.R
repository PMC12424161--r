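#' @include AllClasses.R
NULL

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has_seed)
        assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Docking success rate
#'
#' Fraction of predictions whose heavy-atom RMSD under the chosen alignment
#' reference is at most the threshold (inclusive), in percent.
#'
#' @param values numeric RMSDs in nm.
#' @param threshold success threshold in nm (default 0.2).
#' @return list with `n`, `successes`, `rate` (percent).
#' @examples
#' successRate(c(0.1, 0.3))$rate   # 50
#' @export
successRate <- function(values, threshold = 0.2) {
    if (!length(values)) stop("success rate of an empty sample is undefined")
    if (anyNA(values)) stop("RMSD values must not be NA")
    s <- sum(values <= threshold)
    list(n = length(values), successes = s,
         rate = 100 * s / length(values))
}

#' Percentile bootstrap CI for a binary success rate
#'
#' Percentile bootstrap of the mean of a 0/1 outcome vector.  For binary
#' data the resampled sum is exactly Binomial(n, phat), so replicates are
#' drawn directly from that distribution; non-binary vectors fall back to
#' explicit index resampling.  Reproducible given `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param outcomes numeric vector (0/1 for success indicators).
#' @param nResamples bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(low, high)` in percent.
#' @export
bootstrapCI <- function(outcomes, nResamples = 10000, level = 0.95,
                        seed = 20250826) {
    n <- length(outcomes)
    if (n < 1L) stop("need at least one outcome")
    alpha <- (1 - level) / 2
    means <- .withSeed(seed, {
        if (all(outcomes %in% c(0, 1)))
            stats::rbinom(nResamples, n, mean(outcomes)) / n
        else
            vapply(seq_len(nResamples), function(i)
                mean(outcomes[sample.int(n, n, replace = TRUE)]),
                numeric(1))
    })
    as.numeric(100 * stats::quantile(means, c(alpha, 1 - alpha),
                                     names = FALSE, type = 7))
}

.stars <- function(p) {
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
    else ""
}

#' Welch's two-sample t-test on success indicators
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom) on two
#' outcome vectors, with the conventional significance stars (* p<0.05,
#' ** p<0.01, *** p<0.001).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `stars`.
#' @export
welchTest <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each sample needs at least 2 observations")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b))))
            stop("degenerate: both samples constant and equal")
        stop("degenerate: both samples have zero variance")
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, stars = .stars(ht$p.value))
}

.refColumn <- c(backbone = "rmsd_backbone", pocket = "rmsd_pocket",
                ligand = "rmsd_ligand", pal = "rmsd_pal")

.tableRecords <- function(table) {
    if (is(table, "EvaluationTable")) records(table) else table
}

## Per-entry minimum of a reference metric over ranks 1..n for one method.
.entryMinima <- function(df, method, n, reference) {
    col <- .refColumn[[match.arg(reference, names(.refColumn))]]
    df <- df[df$method == method & df$rank <= n, , drop = FALSE]
    if (!nrow(df)) return(numeric(0))
    vapply(split(df[[col]], df$entry_id), min, numeric(1))
}

#' Top-N success rate
#'
#' Per system, the prediction counts as a success when the minimum of the
#' reference metric over the top `n` ranked poses is at most the threshold;
#' `n` larger than the available pose count simply uses all poses.
#'
#' @param table an \linkS4class{EvaluationTable} (or its records
#'   data.frame).
#' @param n number of top-ranked poses considered.
#' @param reference `"backbone"`, `"pocket"`, `"ligand"` or `"pal"`.
#' @param threshold success threshold in nm.
#' @param method method label evaluated (default: the single method present).
#' @param ci compute a bootstrap CI (default TRUE).
#' @param seed,nResamples bootstrap parameters, see [bootstrapCI()].
#' @return one-row data.frame: method, strategy, reference, n, successes,
#'   rate, ci_low, ci_high; the per-entry 0/1 outcomes are attached as
#'   attribute `"outcomes"`.
#' @export
topnSuccess <- function(table, n = 5L, reference = "pal", threshold = 0.2,
                        method = NULL, ci = TRUE, seed = 20250826,
                        nResamples = 10000) {
    df <- .tableRecords(table)
    if (is.null(method)) {
        method <- unique(df$method)
        if (length(method) != 1L)
            stop("several methods present; pick one with `method=`")
    }
    mins <- .entryMinima(df, method, n, reference)
    if (!length(mins)) stop("no poses for method ", method)
    outcomes <- as.numeric(mins <= threshold)
    sr <- successRate(mins, threshold)
    civ <- if (ci) bootstrapCI(outcomes, nResamples, seed = seed)
           else c(NA_real_, NA_real_)
    out <- data.frame(method = method, strategy = sprintf("Top-%d", n),
                      reference = reference, n = sr$n,
                      successes = sr$successes, rate = sr$rate,
                      ci_low = civ[1L], ci_high = civ[2L],
                      stringsAsFactors = FALSE)
    attr(out, "outcomes") <- outcomes
    out
}

#' Hybrid (multi-method) Top-N success rate
#'
#' Per system, the candidate set is the union of each listed method's top
#' `n` poses; success is a minimum over that union at most the threshold.
#' Systems lacking poses for any listed method are excluded with a warning.
#'
#' @inheritParams topnSuccess
#' @param methods character vector of method labels to combine.
#' @return as [topnSuccess()], with a `strategy` like
#'   `"AF3-Top5 + Vina-Top5"`.
#' @export
hybridSuccess <- function(table, methods, n = 5L, reference = "pal",
                          threshold = 0.2, ci = TRUE, seed = 20250826,
                          nResamples = 10000) {
    df <- .tableRecords(table)
    per <- lapply(methods, function(m) .entryMinima(df, m, n, reference))
    common <- Reduce(intersect, lapply(per, names))
    dropped <- setdiff(unique(df$entry_id), common)
    if (length(dropped))
        warning(length(dropped),
                " entries lack poses for some method; excluded")
    if (!length(common)) stop("no entry has poses for every method")
    mins <- do.call(pmin, lapply(per, function(v) v[common]))
    outcomes <- as.numeric(mins <= threshold)
    sr <- successRate(mins, threshold)
    civ <- if (ci) bootstrapCI(outcomes, nResamples, seed = seed)
           else c(NA_real_, NA_real_)
    out <- data.frame(method = paste(methods, collapse = "+"),
                      strategy = paste(sprintf("%s-Top%d", methods, n),
                                       collapse = " + "),
                      reference = reference, n = sr$n,
                      successes = sr$successes, rate = sr$rate,
                      ci_low = civ[1L], ci_high = civ[2L],
                      stringsAsFactors = FALSE)
    attr(out, "outcomes") <- outcomes
    out
}

#' Decompose a failed prediction into failure modes
#'
#' Applied to poses failing the pocket-aligned ligand criterion.  The
#' constituent metrics assign non-exclusive causes: `ligand_structure` when
#' the ligand-aligned RMSD also fails, `pocket_structure` when the pocket
#' RMSD also fails, `both` when both do, and `orientation` — the residual
#' mode — when ligand and pocket are each fine yet the placement fails.
#' Categories deliberately overlap (a record can be both a ligand and a
#' pocket failure), so reported proportions may exceed 100%.
#'
#' @param m a \linkS4class{PoseMetrics}, or a data.frame row with columns
#'   rmsd_ligand, rmsd_pocket, rmsd_pal.
#' @param threshold RMSD threshold in nm (default 0.2).
#' @return `NULL` when the pose passes the pocket-aligned criterion, else a
#'   named logical vector `c(orientation=, ligand_structure=,
#'   pocket_structure=, both=)`.
#' @export
classifyFailure <- function(m, threshold = 0.2) {
    if (is(m, "PoseMetrics"))
        m <- poseMetricsRow(m)
    if (m$rmsd_pal <= threshold) return(NULL)
    lig <- m$rmsd_ligand > threshold
    poc <- m$rmsd_pocket > threshold
    c(orientation = !lig && !poc, ligand_structure = lig,
      pocket_structure = poc, both = lig && poc)
}

#' Failure-mode proportions of an evaluation table
#'
#' Applies [classifyFailure()] to the best pose (rank 1) of each system and
#' method, and tabulates the share of each (non-exclusive) mode among
#' failures, with percentile-bootstrap CIs over failed systems.
#'
#' @inheritParams topnSuccess
#' @param rank which rank to assess (default 1, the engine's best pose).
#' @return data.frame with one row per mode: method, mode, count,
#'   n_failures, share (percent), ci_low, ci_high.
#' @export
failureModes <- function(table, threshold = 0.2, method = NULL, rank = 1L,
                         seed = 20250826, nResamples = 10000) {
    df <- .tableRecords(table)
    if (is.null(method)) {
        method <- unique(df$method)
        if (length(method) != 1L)
            stop("several methods present; pick one with `method=`")
    }
    df <- df[df$method == method & df$rank == rank, , drop = FALSE]
    flags <- lapply(seq_len(nrow(df)), function(i)
        classifyFailure(df[i, , drop = FALSE], threshold))
    flags <- flags[!vapply(flags, is.null, logical(1))]
    modes <- c("orientation", "ligand_structure", "pocket_structure", "both")
    if (!length(flags))
        return(data.frame(method = method, mode = modes, count = 0L,
                          n_failures = 0L, share = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_))
    mat <- do.call(rbind, flags)
    out <- lapply(seq_along(modes), function(k) {
        v <- as.numeric(mat[, modes[k]])
        ciy <- bootstrapCI(v, nResamples, seed = seed + k)
        data.frame(method = method, mode = modes[k],
                   count = as.integer(sum(v)),
                   n_failures = length(v), share = 100 * mean(v),
                   ci_low = ciy[1L], ci_high = ciy[2L],
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Aggregate success summaries with group comparisons
#'
#' Produces one success-summary row per method x split x alignment
#' reference x strategy (Best pose and Top-N), optionally further split by a
#' PFAS grouping column (e.g. `charge_category`), each with a bootstrap CI;
#' plus Welch Before-vs-After comparisons on the 0/1 success indicators.
#'
#' @inheritParams topnSuccess
#' @param topN the Top-N strategy size (default 5).
#' @param groupBy optional extra grouping column of the records (e.g.
#'   `"charge_category"`).
#' @param references alignment references to aggregate.
#' @return list with data.frames `summary` and `comparisons`.
#' @export
aggregateReport <- function(table, threshold = 0.2, topN = 5L,
                            groupBy = NULL,
                            references = c("backbone", "pocket", "ligand",
                                           "pal"),
                            seed = 20250826, nResamples = 10000) {
    df <- .tableRecords(table)
    if (!"split" %in% names(df)) df$split <- "All"
    groups <- if (is.null(groupBy)) list(All = df) else
        split(df, df[[groupBy]])
    rows <- list()
    comps <- list()
    subSeeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                           1e4))
    k <- 0L
    for (gname in names(groups)) {
        gdf <- groups[[gname]]
        for (m in unique(gdf$method)) {
            for (ref in references) {
                for (strat_n in c(1L, topN)) {
                    bySplit <- list()
                    for (s in unique(gdf$split)) {
                        sdf <- gdf[gdf$split == s, , drop = FALSE]
                        if (!nrow(sdf)) next
                        k <- k + 1L
                        r <- topnSuccess(sdf, n = strat_n, reference = ref,
                                         threshold = threshold, method = m,
                                         seed = subSeeds[k],
                                         nResamples = nResamples)
                        r$strategy <- if (strat_n == 1L) "Best" else
                            sprintf("Top-%d", strat_n)
                        r$split <- s
                        r$group <- gname
                        bySplit[[s]] <- r
                        rows[[length(rows) + 1L]] <- r
                    }
                    if (all(c("Before", "After") %in% names(bySplit))) {
                        a <- attr(bySplit[["Before"]], "outcomes")
                        b <- attr(bySplit[["After"]], "outcomes")
                        wt <- tryCatch(welchTest(a, b),
                                       error = function(e) NULL)
                        if (!is.null(wt))
                            comps[[length(comps) + 1L]] <- data.frame(
                                group = gname, method = m, reference = ref,
                                strategy = if (strat_n == 1L) "Best" else
                                    sprintf("Top-%d", strat_n),
                                t = wt$t, df = wt$df, p = wt$p,
                                stars = wt$stars, stringsAsFactors = FALSE)
                    }
                }
            }
        }
    }
    summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    attr(summary, "outcomes") <- NULL
    comparisons <- if (length(comps))
        do.call(rbind, c(comps, list(make.row.names = FALSE)))
    else data.frame()
    list(summary = summary, comparisons = comparisons)
}
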