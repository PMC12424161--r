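#' @include AllClasses.R
NULL

#' Construct dataset-manifest entries
#'
#' One row per candidate protein-PFAS system.  `pfas_ligand_ids` and any
#' per-method pose paths are stored as semicolon-separated strings so the
#' manifest stays a flat CSV/JSON-friendly table.
#'
#' @param entry_id character entry identifiers.
#' @param release_date ISO-8601 dates (character or Date).
#' @param n_protein_chains,n_residues integers.
#' @param has_nonstandard_aa logical.
#' @param pfas_ligand_ids character, `;`-separated ligand codes.
#' @param ... further columns (e.g. native_path, poses_AF3) recycled in.
#' @return data.frame manifest
#' @export
datasetEntry <- function(entry_id, release_date, n_protein_chains = 1L,
                         n_residues = NA_integer_,
                         has_nonstandard_aa = FALSE,
                         pfas_ligand_ids = "", ...) {
    data.frame(entry_id = entry_id,
               release_date = as.character(release_date),
               n_protein_chains = as.integer(n_protein_chains),
               n_residues = as.integer(n_residues),
               has_nonstandard_aa = has_nonstandard_aa,
               pfas_ligand_ids = pfas_ligand_ids, ...,
               stringsAsFactors = FALSE)
}

.splitIDs <- function(x) {
    out <- strsplit(as.character(x), ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(trimws(v))])
}

#' Apply the dataset inclusion filters
#'
#' An entry is kept when it has exactly one protein chain, exactly one PFAS
#' ligand (in strict single-ligand mode), strictly more than `minResidues`
#' residues, and no nonstandard amino acids.  Every violated rule is
#' reported, not just the first.
#'
#' @param entries manifest data.frame (see [datasetEntry()]).
#' @param strictSingleLigand require exactly one PFAS ligand id (default
#'   `TRUE`).
#' @param minResidues residue-count threshold; kept entries satisfy
#'   `n_residues > minResidues` (default 50, strict inequality).
#' @return the manifest with logical column `keep` and character column
#'   `reasons` (`;`-separated) appended.
#' @export
filterEntries <- function(entries, strictSingleLigand = TRUE,
                          minResidues = 50L) {
    nlig <- lengths(.splitIDs(entries$pfas_ligand_ids))
    reasons <- vector("list", nrow(entries))
    add <- function(idx, msg) for (i in which(idx))
        reasons[[i]] <<- c(reasons[[i]], msg)
    add(entries$n_protein_chains != 1L, "protein chain count not 1")
    if (strictSingleLigand)
        add(nlig != 1L, "PFAS ligand count not 1")
    else
        add(nlig < 1L, "no PFAS ligand")
    add(!(entries$n_residues > minResidues),
        sprintf("residue count not > %d", minResidues))
    add(!is.na(entries$has_nonstandard_aa) &
            as.logical(entries$has_nonstandard_aa),
        "nonstandard amino acids")
    entries$keep <- lengths(reasons) == 0L
    entries$reasons <- vapply(reasons, paste, character(1), collapse = "; ")
    entries
}

#' Split manifest entries by structure release date
#'
#' Entries released on or before the cutoff form the "Before" set (seen by
#' the predictor during training); entries released after it form the
#' "After" set.  Entries whose date does not parse are returned separately
#' with a warning, so `before + after + errors` always partitions the input.
#'
#' @param entries manifest data.frame with a `release_date` column
#'   (ISO-8601).
#' @param cutoff cutoff date (default `"2021-09-30"`); the cutoff day itself
#'   is assigned to Before.
#' @return list with data.frames `before`, `after`, `errors`.
#' @export
splitByDate <- function(entries, cutoff = as.Date("2021-09-30")) {
    cutoff <- as.Date(cutoff)
    d <- suppressWarnings(as.Date(as.character(entries$release_date),
                                  format = "%Y-%m-%d"))
    bad <- is.na(d)
    if (any(bad))
        warning(sum(bad), " entries with unparseable release dates excluded")
    list(before = entries[!bad & d <= cutoff, , drop = FALSE],
         after = entries[!bad & d > cutoff, , drop = FALSE],
         errors = entries[bad, , drop = FALSE])
}

#' Label manifest entries with their split
#'
#' @inheritParams splitByDate
#' @return character vector `"Before"`/`"After"` (`NA` for unparseable
#'   dates).
#' @export
splitLabels <- function(entries, cutoff = as.Date("2021-09-30")) {
    d <- suppressWarnings(as.Date(as.character(entries$release_date),
                                  format = "%Y-%m-%d"))
    ifelse(is.na(d), NA_character_,
           ifelse(d <= as.Date(cutoff), "Before", "After"))
}

#' Read a dataset manifest
#'
#' CSV or JSON with at least columns entry_id, release_date (ISO-8601);
#' typically also ligand_id, native_path and one `poses_<method>` column of
#' `;`-separated pose file paths per method.
#'
#' @param path manifest file.
#' @return data.frame manifest
#' @export
readManifest <- function(path) {
    ext <- tolower(tools::file_ext(path))
    man <- if (ext == "json")
        as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
    else
        utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("entry_id", "release_date") %in% names(man)))
        stop("manifest needs at least entry_id and release_date columns")
    man
}

#' Load the bundled CF2-CF benchmark table
#'
#' The package ships the 18-system worked-example benchmark of
#' protein-PFAS complexes whose ligands carry the -CF2-CF- motif: entry
#' ids, ligand codes, release dates (US M/D/YYYY in the source, parsed to
#' ISO here — this loader is the only place that format is accepted), and
#' per-method RMSD columns (nm) for the four alignment references.
#'
#' @return data.frame with ISO `release_date` and numeric RMSD columns.
#' @export
readBenchmarkTable <- function() {
    path <- system.file("extdata", "cf2cf_benchmark.csv",
                        package = "pfasbench")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    d <- as.Date(tab$release_date, format = "%m/%d/%Y")
    if (anyNA(d)) stop("bundled benchmark table has unparseable dates")
    tab$release_date <- format(d, "%Y-%m-%d")
    tab
}
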