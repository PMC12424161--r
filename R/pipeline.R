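#' @include AllClasses.R structure-io.R correspondence.R pose-metrics.R
#' @include curation.R evaluation-stats.R
NULL

#' Assemble a pipeline run configuration
#'
#' @param manifest path to a dataset manifest (see [readManifest()]).
#' @param outputDir directory for report artifacts (created if missing).
#' @param threshold success threshold in nm.
#' @param pocketCutoff pocket radius in nm.
#' @param topN Top-N strategy size.
#' @param splitCutoff release-date cutoff separating Before/After.
#' @param nResamples bootstrap resamples.
#' @param seed integer seed for all stochastic steps.
#' @param ligandMode ligand correspondence mode ([mapLigandAtoms()]).
#' @param strictLigand strict single-ligand reading of native files.
#' @return a validated config list of class `pfas_run_config`.
#' @export
runConfig <- function(manifest, outputDir = "pfasbench-out",
                      threshold = 0.2, pocketCutoff = 1.0, topN = 5L,
                      splitCutoff = "2021-09-30", nResamples = 10000,
                      seed = 20250826, ligandMode = "name_order",
                      strictLigand = TRUE) {
    stopifnot(threshold > 0, pocketCutoff > 0, topN >= 1L, nResamples >= 1)
    structure(list(manifest = manifest, outputDir = outputDir,
                   threshold = threshold, pocketCutoff = pocketCutoff,
                   topN = as.integer(topN),
                   splitCutoff = as.character(splitCutoff),
                   nResamples = nResamples, seed = as.integer(seed),
                   ligandMode = ligandMode, strictLigand = strictLigand),
              class = "pfas_run_config")
}

.poseColumns <- function(man) {
    cols <- grep("^poses_", names(man), value = TRUE)
    if (!length(cols)) stop("manifest has no poses_<method> columns")
    cols
}

#' Run the full evaluation pipeline
#'
#' Reads the manifest, evaluates every pose of every method against its
#' native complex (four-reference RMSDs), labels entries with the
#' Before/After split, aggregates success summaries with bootstrap CIs and
#' Welch comparisons, decomposes failures into modes, and writes the
#' artifact files `metrics.csv`, `success_summary.csv`, `failure_modes.csv`,
#' `comparisons.json` and `run_log.json` into the output directory.
#' Unreadable pose files skip the affected pose with a logged warning;
#' reruns with the same config produce identical CSVs.
#'
#' @param config a config from [runConfig()].
#' @return (invisibly) a list with the evaluation table, report and artifact
#'   paths.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pfas_run_config"))
    man <- readManifest(config$manifest)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    poseCols <- .poseColumns(man)
    warnings_n <- 0L
    rows <- list()
    for (i in seq_len(nrow(man))) {
        native <- tryCatch(
            readComplex(man$native_path[i],
                        ligand = if ("ligand_id" %in% names(man))
                            man$ligand_id[i] else NULL,
                        strict = config$strictLigand,
                        entryID = man$entry_id[i]),
            error = function(e) {
                warning("entry ", man$entry_id[i], " skipped: ",
                        conditionMessage(e))
                NULL
            })
        if (is.null(native)) { warnings_n <- warnings_n + 1L; next }
        pocket <- definePocket(native, config$pocketCutoff)
        for (pc in poseCols) {
            method <- sub("^poses_", "", pc)
            paths <- strsplit(as.character(man[[pc]][i]), ";")[[1]]
            paths <- trimws(paths[nzchar(trimws(paths))])
            rank <- 0L
            for (p in paths) {
                rank <- rank + 1L
                row <- tryCatch({
                    pred <- readLigandPose(native, p)
                    corr <- buildCorrespondence(native, pred,
                                                ligandMode =
                                                    config$ligandMode)
                    m <- evaluatePose(native, pred, pocket, corr,
                                      rank = rank, methodLabel = method)
                    poseMetricsRow(m, man$entry_id[i])
                }, error = function(e) {
                    warning("pose ", p, " skipped: ", conditionMessage(e))
                    NULL
                })
                if (is.null(row)) {
                    warnings_n <- warnings_n + 1L
                    rank <- rank - 1L          # keep ranks contiguous
                } else rows[[length(rows) + 1L]] <- row
            }
        }
    }
    if (!length(rows)) stop("no pose could be evaluated")
    df <- do.call(rbind, rows)
    if ("release_date" %in% names(man)) {
        lab <- splitLabels(man, cutoff = as.Date(config$splitCutoff))
        df$split <- lab[match(df$entry_id, man$entry_id)]
    }
    tab <- EvaluationTable(df)
    report <- aggregateReport(tab, threshold = config$threshold,
                              topN = config$topN, seed = config$seed,
                              nResamples = config$nResamples)
    fm <- do.call(rbind, lapply(unique(df$method), function(m)
        failureModes(tab, threshold = config$threshold, method = m,
                     seed = config$seed, nResamples = config$nResamples)))
    paths <- list(
        metrics = file.path(config$outputDir, "metrics.csv"),
        summary = file.path(config$outputDir, "success_summary.csv"),
        failures = file.path(config$outputDir, "failure_modes.csv"),
        comparisons = file.path(config$outputDir, "comparisons.json"),
        log = file.path(config$outputDir, "run_log.json"))
    utils::write.csv(df, paths$metrics, row.names = FALSE)
    utils::write.csv(report$summary, paths$summary, row.names = FALSE)
    utils::write.csv(fm, paths$failures, row.names = FALSE)
    jsonlite::write_json(report$comparisons, paths$comparisons,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    log <- list(config = unclass(config),
                seed = config$seed,
                n_entries = nrow(man), n_poses = nrow(df),
                n_warnings = warnings_n,
                package_version =
                    as.character(utils::packageVersion("pfasbench")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA)
    invisible(list(table = tab, report = report, failure_modes = fm,
                   paths = paths))
}

#' Write a synthetic benchmark to disk
#'
#' Generates `nSystems` toy native complexes, perturbed poses for two
#' pseudo-methods, and a manifest ready for [runPipeline()] — an end-to-end
#' dry run of the whole pipeline with no docking engine involved.
#'
#' @param dir output directory.
#' @param nSystems number of systems.
#' @param nPoses poses per method and system.
#' @param seed integer seed.
#' @return path to the written manifest CSV.
#' @export
simulateBenchmark <- function(dir, nSystems = 5L, nPoses = 3L, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    modes <- c("ligand_rigid", "ligand_internal", "pocket_noise")
    mags <- c(ligand_rigid = 0.35, ligand_internal = 100, pocket_noise = 0.3)
    man <- vector("list", nSystems)
    subSeeds <- .withSeed(seed, matrix(sample.int(1e6, 2 * nSystems *
                                                      nPoses),
                                       nrow = nSystems))
    dates <- .withSeed(seed + 1L, sample(seq(as.Date("2015-01-01"),
                                             as.Date("2024-12-31"), by = 1),
                                         nSystems))
    for (s in seq_len(nSystems)) {
        native <- makeToyComplex(seed = seed + s, nResidues = 24L)
        npath <- file.path(dir, sprintf("native_%03d.pdb", s))
        writeComplex(native, npath)
        posePaths <- list(EngineA = character(), EngineB = character())
        for (m in seq_along(names(posePaths))) {
            for (k in seq_len(nPoses)) {
                mode <- modes[(s + k + m) %% length(modes) + 1L]
                ps <- perturbationSpec(mode, mags[[mode]],
                                       seed = subSeeds[s, (m - 1L) *
                                                              nPoses + k])
                pred <- perturb(native, ps)
                ppath <- file.path(dir, sprintf("pose_%03d_%s_%d.pdb",
                                                s, names(posePaths)[m], k))
                writeComplex(pred, ppath)
                posePaths[[m]] <- c(posePaths[[m]], ppath)
            }
        }
        man[[s]] <- data.frame(
            entry_id = entryID(native), ligand_id = "PFA",
            release_date = format(dates[s], "%Y-%m-%d"),
            native_path = npath,
            poses_EngineA = paste(posePaths$EngineA, collapse = ";"),
            poses_EngineB = paste(posePaths$EngineB, collapse = ";"),
            stringsAsFactors = FALSE)
    }
    mpath <- file.path(dir, "manifest.csv")
    utils::write.csv(do.call(rbind, man), mpath, row.names = FALSE)
    mpath
}
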