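## Readers/writers for the study's tabular formats. All files are UTF-8
## CSV with one header row; the literal "n.d." encodes a nondetect and a
## logical above_calibration column flags values extrapolated beyond the
## calibration range (kept, but semi-quantitative).

#' @importFrom utils read.csv write.csv
NULL

.readCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

.requireCols <- function(df, cols, what) {
    missing <- setdiff(cols, colnames(df))
    if (length(missing))
        stop("schema error in ", what, ": missing column(s) ",
             paste(missing, collapse = ", "))
}

#' Read the compound registry
#'
#' Reads `compounds.csv` (one row per target analyte) and validates all
#' registry invariants: unique ids, known substance groups, positive molar
#' masses, non-negative MDLs, positive partition and effect
#' concentrations where present. Optional numeric fields left blank are
#' stored as `NA`.
#'
#' @param path path to a compounds CSV with at least the columns
#'   `compound_id, name, group, molar_mass_g_mol, mdl_pg_mg`.
#' @return a [CompoundRegistry].
#' @export
readCompoundRegistry <- function(path) {
    df <- .readCsv(path)
    .requireCols(df, .REGISTRY_REQUIRED, "compound registry")
    bad <- which(!is.finite(df$molar_mass_g_mol) | df$molar_mass_g_mol <= 0)
    if (length(bad))
        stop("validation error: non-positive molar mass in row(s) ",
             paste(bad, collapse = ", "))
    if ("effect_tested" %in% colnames(df))
        df$effect_tested <- as.logical(df$effect_tested)
    out <- as(DataFrame(df), "CompoundRegistry")
    validObject(out)
    rownames(out) <- out$compound_id
    out
}

#' Write a compound registry to CSV
#' @param registry a [CompoundRegistry].
#' @param path output file path.
#' @export
writeCompoundRegistry <- function(registry, path) {
    write.csv(as.data.frame(registry), path, row.names = FALSE, na = "")
    invisible(path)
}

#' Read the sample annotation table
#'
#' @param path path to a samples CSV with columns
#'   `sample_id, animal_id, species, organ, lipid_fraction, pdms_mass_mg,
#'   lipid_uptake_fraction`.
#' @return a [SampleTable].
#' @export
readSampleTable <- function(path) {
    df <- .readCsv(path)
    .requireCols(df, .SAMPLE_REQUIRED, "sample table")
    out <- as(DataFrame(df), "SampleTable")
    validObject(out)
    rownames(out) <- out$sample_id
    out
}

#' Write a sample table to CSV
#' @param samples a [SampleTable].
#' @param path output file path.
#' @export
writeSampleTable <- function(samples, path) {
    write.csv(as.data.frame(samples), path, row.names = FALSE, na = "")
    invisible(path)
}

#' Read a long-format concentration table
#'
#' Reads `concentrations.csv` with columns `sample_id, compound_id,
#' c_pdms_pg_mg` and optionally `above_calibration` (logical) and
#' `replicate`. The literal `"n.d."` (or an empty cell) encodes a
#' nondetect. Replicate PDMS sheets of the same extract are averaged to
#' one value per (compound, sample) at read time: the arithmetic mean
#' over detected replicates, nondetect only when all replicates are
#' nondetect, and flagged above calibration when any replicate is.
#'
#' Every `compound_id` must resolve against the registry and every
#' `sample_id` against the sample table; unknown keys are an error, never
#' silently skipped. Pairs absent from the file are nondetects.
#'
#' @param path path to the concentrations CSV.
#' @param registry a [CompoundRegistry].
#' @param samples a [SampleTable].
#' @return a raw (uncensored) [ConcentrationTable-class].
#' @export
readConcentrationTable <- function(path, registry, samples) {
    df <- .readCsv(path)
    .requireCols(df, c("sample_id", "compound_id", "c_pdms_pg_mg"),
                 "concentration table")
    unknown <- setdiff(unique(df$compound_id), registry$compound_id)
    if (length(unknown))
        stop("unknown compound_id in concentration table: ",
             paste(unknown, collapse = ", "))
    unknown <- setdiff(unique(df$sample_id), samples$sample_id)
    if (length(unknown))
        stop("unknown sample_id in concentration table: ",
             paste(unknown, collapse = ", "))

    raw <- as.character(df$c_pdms_pg_mg)
    nd <- is.na(raw) | trimws(raw) %in% c("n.d.", "nd", "")
    val <- suppressWarnings(as.numeric(raw))
    if (any(!nd & is.na(val)))
        stop("non-numeric concentration that is not 'n.d.' in row(s) ",
             paste(which(!nd & is.na(val)), collapse = ", "))
    if (any(!nd & val < 0, na.rm = TRUE))
        stop("negative concentration in row(s) ",
             paste(which(!nd & val < 0), collapse = ", "))
    above <- if ("above_calibration" %in% colnames(df))
        as.logical(df$above_calibration) & !nd else rep(FALSE, nrow(df))
    above[is.na(above)] <- FALSE

    conc <- matrix(NA_real_, nrow(registry), nrow(samples),
                   dimnames = list(registry$compound_id, samples$sample_id))
    status <- matrix("nondetect", nrow(registry), nrow(samples),
                     dimnames = dimnames(conc))
    key <- paste(df$compound_id, df$sample_id, sep = "\r")
    for (k in unique(key)) {
        i <- which(key == k)
        cid <- df$compound_id[i[1L]]
        sid <- df$sample_id[i[1L]]
        det <- i[!nd[i]]
        if (length(det)) {
            conc[cid, sid] <- mean(val[det])
            status[cid, sid] <- if (any(above[det])) "above_calibration"
                                else "detected"
        }
    }
    ConcentrationTable(conc, status, registry, samples)
}

#' Write a concentration table to long-format CSV
#'
#' Inverse of [readConcentrationTable()]: one row per (sample, compound)
#' pair, nondetects written as `"n.d."`, above-calibration entries
#' flagged in a logical column. Reading the file back reproduces values
#' and statuses exactly.
#'
#' @param x a [ConcentrationTable-class].
#' @param path output file path.
#' @export
writeConcentrationTable <- function(x, path) {
    cc <- concMatrix(x)
    st <- statusMatrix(x)
    df <- data.frame(
        sample_id = rep(colnames(cc), each = nrow(cc)),
        compound_id = rep(rownames(cc), times = ncol(cc)),
        c_pdms_pg_mg = ifelse(is.na(as.vector(cc)), "n.d.",
                              formatC(as.vector(cc), digits = 17,
                                      format = "g")),
        above_calibration = as.vector(st) == "above_calibration",
        stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read the bioassay results table
#'
#' @param path path to a bioassays CSV with columns `sample_id, assay,
#'   endpoint, ec_extract_kg_l, reference_compound, ec_reference_mol_l`.
#' @param samples optional [SampleTable]; when given, every `sample_id`
#'   must resolve against it.
#' @return a [BioassayPanel].
#' @export
readBioassayPanel <- function(path, samples = NULL) {
    df <- .readCsv(path)
    out <- as(DataFrame(df), "BioassayPanel")
    validObject(out)
    if (!is.null(samples)) {
        unknown <- setdiff(unique(out$sample_id), samples$sample_id)
        if (length(unknown))
            stop("unknown sample_id in bioassay table: ",
                 paste(unknown, collapse = ", "))
    }
    out
}

#' Write a bioassay panel to CSV
#' @param panel a [BioassayPanel].
#' @param path output file path.
#' @export
writeBioassayPanel <- function(panel, path) {
    write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
    invisible(path)
}

#' Validate a full study for internal consistency
#'
#' Checks the cross-table invariants a complete study must satisfy:
#' object validity of all parts, row/column alignment of the
#' concentration table, and -- when the table reports itself censored --
#' that every detected value is at or above its compound's MDL.
#'
#' @param conc a [ConcentrationTable-class].
#' @param bioassays an optional [BioassayPanel].
#' @return invisibly `TRUE`; problems raise errors.
#' @export
validateStudy <- function(conc, bioassays = NULL) {
    validObject(conc)
    validObject(compoundData(conc))
    validObject(sampleData(conc))
    if ("censored" %in% pipelineStages(conc)) {
        cc <- concMatrix(conc)
        mdl <- compoundData(conc)$mdl_pg_mg
        bad <- which(!is.na(cc) & cc < mdl, arr.ind = TRUE)
        if (nrow(bad))
            stop("censored table carries detected values below MDL for: ",
                 paste(unique(rownames(cc)[bad[, 1L]]), collapse = ", "))
    }
    if (!is.null(bioassays)) {
        validObject(bioassays)
        unknown <- setdiff(unique(bioassays$sample_id),
                           sampleData(conc)$sample_id)
        if (length(unknown))
            stop("bioassay rows reference unknown sample_id: ",
                 paste(unknown, collapse = ", "))
    }
    invisible(TRUE)
}
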