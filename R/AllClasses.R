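#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- isEmpty
#' @importClassesFrom S4Vectors DFrame
#' @import SummarizedExperiment
NULL

## controlled vocabularies used throughout
.COMPOUND_GROUPS <- c("PCB", "PAH", "OCP", "BDE", "Pyrethroid", "CHC",
                      "Musk", "Other")
.SPECIES <- c("harbor_porpoise", "harbor_seal", "ringed_seal", "orca")
.ORGANS <- c("blubber", "liver", "brain", "kidney")
.STATUS <- c("detected", "nondetect", "above_calibration")
.ASSAYS <- c("ahr_calux", "arec32", "pparg_bla")
.ENDPOINTS <- c("activation", "cytotoxicity")

.REGISTRY_REQUIRED <- c("compound_id", "name", "group", "molar_mass_g_mol",
                        "mdl_pg_mg")
.SAMPLE_REQUIRED <- c("sample_id", "animal_id", "species", "organ",
                      "lipid_fraction", "pdms_mass_mg",
                      "lipid_uptake_fraction")

#' Registry of target analytes
#'
#' A `DataFrame` subclass holding one row per target compound: identity
#' (`compound_id`, `name`), substance `group`, molar mass (g/mol), method
#' detection limit (pg analyte per mg PDMS), optional physicochemical
#' properties (`k_lipid_pdms`, the experimental lipid/PDMS partition
#' coefficient; `log_kow`; `log_k_medium_air`, the log10 bioassay-medium/air
#' partition coefficient governing volatility losses from test wells), a
#' logical `effect_tested` flag and optional per-assay effect-concentration
#' columns (`ec_<assay>_mol_l` for activation, `ic_<assay>_mol_l` for
#' cytotoxicity, in mol/L bioassay medium; `NA` means tested but inactive,
#' or untested when `effect_tested` is `FALSE`).
#'
#' @seealso [readCompoundRegistry()]
#' @export
setClass("CompoundRegistry", contains = "DFrame")

setValidity("CompoundRegistry", function(object) {
    msg <- character()
    missing <- setdiff(.REGISTRY_REQUIRED, colnames(object))
    if (length(missing))
        return(paste("missing required column(s):",
                     paste(missing, collapse = ", ")))
    id <- object$compound_id
    if (anyDuplicated(id))
        msg <- c(msg, paste("duplicate compound_id:",
                            paste(unique(id[duplicated(id)]), collapse = ", ")))
    bad <- !object$group %in% .COMPOUND_GROUPS
    if (any(bad))
        msg <- c(msg, paste("unknown group(s):",
                            paste(unique(object$group[bad]), collapse = ", ")))
    if (any(!is.finite(object$molar_mass_g_mol) | object$molar_mass_g_mol <= 0))
        msg <- c(msg, "molar_mass_g_mol must be finite and > 0")
    if (any(is.na(object$mdl_pg_mg) | object$mdl_pg_mg < 0))
        msg <- c(msg, "mdl_pg_mg must be >= 0")
    if ("k_lipid_pdms" %in% colnames(object)) {
        k <- object$k_lipid_pdms
        if (any(!is.na(k) & k <= 0))
            msg <- c(msg, "k_lipid_pdms must be > 0 when present")
    }
    ec_cols <- grep("^(ec|ic)_.*_mol_l$", colnames(object), value = TRUE)
    for (cc in ec_cols) {
        v <- object[[cc]]
        if (any(!is.na(v) & v <= 0))
            msg <- c(msg, paste(cc, "must be > 0 when present"))
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Sample (tissue extract) annotation table
#'
#' One row per chemometer extract: `sample_id`, `animal_id`, `species`,
#' `organ`, gravimetric `lipid_fraction` (g lipid / g tissue, in \[0,1\]),
#' `pdms_mass_mg` (total PDMS sheet mass) and `lipid_uptake_fraction`
#' (g co-extracted lipid taken up by the polymer per g PDMS).
#'
#' @export
setClass("SampleTable", contains = "DFrame")

setValidity("SampleTable", function(object) {
    msg <- character()
    missing <- setdiff(.SAMPLE_REQUIRED, colnames(object))
    if (length(missing))
        return(paste("missing required column(s):",
                     paste(missing, collapse = ", ")))
    if (anyDuplicated(object$sample_id))
        msg <- c(msg, "duplicate sample_id")
    if (any(!object$species %in% .SPECIES))
        msg <- c(msg, "unknown species")
    if (any(!object$organ %in% .ORGANS))
        msg <- c(msg, "unknown organ")
    lf <- object$lipid_fraction
    if (any(is.na(lf) | lf < 0 | lf > 1))
        msg <- c(msg, "lipid_fraction must lie in [0, 1]")
    if (any(is.na(object$pdms_mass_mg) | object$pdms_mass_mg <= 0))
        msg <- c(msg, "pdms_mass_mg must be > 0")
    lu <- object$lipid_uptake_fraction
    if (any(is.na(lu) | lu < 0))
        msg <- c(msg, "lipid_uptake_fraction must be >= 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Censoring-aware compound-by-sample concentration matrix
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `conc`, the silicone-based concentration c_PDMS in pg analyte per mg PDMS
#' (`NA` for nondetects), and `status`, one of `"detected"`, `"nondetect"`
#' or `"above_calibration"` (value retained but extrapolated beyond the
#' calibration range, hence semi-quantitative). Row metadata is the
#' [CompoundRegistry], column metadata the [SampleTable]. The pipeline
#' stage already applied (blank subtraction, lipid-uptake correction,
#' censoring) is tracked in `metadata()`.
#'
#' @seealso [ConcentrationTable()], [censorTable()], [subtractBlanks()]
#' @export
setClass("ConcentrationTable", contains = "SummarizedExperiment")

setValidity("ConcentrationTable", function(object) {
    msg <- character()
    if (!all(c("conc", "status") %in% assayNames(object)))
        return("assays 'conc' and 'status' are required")
    cc <- assay(object, "conc")
    st <- assay(object, "status")
    if (!all(st %in% .STATUS))
        msg <- c(msg, paste("status values must be one of:",
                            paste(.STATUS, collapse = ", ")))
    nd <- st == "nondetect"
    if (any(!is.na(cc[nd])))
        msg <- c(msg, "nondetect entries must have NA concentration")
    det <- !nd
    if (any(is.na(cc[det]) | cc[det] <= 0))
        msg <- c(msg, "detected entries must have finite concentration > 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Bioassay measurements of whole extracts
#'
#' One row per extract-by-assay-by-endpoint measurement: `sample_id`,
#' `assay` (`ahr_calux`, `arec32`, `pparg_bla`), `endpoint` (`activation`
#' or `cytotoxicity`), `ec_extract_kg_l` (kg PDMS-equivalent extract per L
#' bioassay medium causing the benchmark effect), the assay's
#' `reference_compound` and its `ec_reference_mol_l`.
#'
#' @export
setClass("BioassayPanel", contains = "DFrame")

setValidity("BioassayPanel", function(object) {
    req <- c("sample_id", "assay", "endpoint", "ec_extract_kg_l",
             "reference_compound", "ec_reference_mol_l")
    missing <- setdiff(req, colnames(object))
    if (length(missing))
        return(paste("missing required column(s):",
                     paste(missing, collapse = ", ")))
    msg <- character()
    if (any(!object$assay %in% .ASSAYS))
        msg <- c(msg, "unknown assay")
    if (any(!object$endpoint %in% .ENDPOINTS))
        msg <- c(msg, "unknown endpoint")
    if (any(is.na(object$ec_extract_kg_l) | object$ec_extract_kg_l <= 0))
        msg <- c(msg, "ec_extract_kg_l must be > 0")
    if (any(is.na(object$ec_reference_mol_l) | object$ec_reference_mol_l <= 0))
        msg <- c(msg, "ec_reference_mol_l must be > 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-assay effect-concentration dataset for concentration addition
#'
#' Holds, for one assay endpoint, the reference compound, its effect
#' concentration `ecReference` (mol/L) and a named vector `ec` of
#' per-compound effect concentrations in the same assay (mol/L). Names of
#' `ec` are the compounds with effect data; `NA` marks compounds tested
#' but inactive, which contribute zero potency yet count as "captured".
#'
#' @export
setClass("EffectDataset",
         representation(assay = "character",
                        endpoint = "character",
                        referenceCompound = "character",
                        ecReference = "numeric",
                        ec = "numeric"))

setValidity("EffectDataset", function(object) {
    msg <- character()
    if (length(object@assay) != 1L || !object@assay %in% .ASSAYS)
        msg <- c(msg, "assay must be one of the known assays")
    if (length(object@endpoint) != 1L || !object@endpoint %in% .ENDPOINTS)
        msg <- c(msg, "endpoint must be 'activation' or 'cytotoxicity'")
    if (length(object@ecReference) != 1L || is.na(object@ecReference) ||
        object@ecReference <= 0)
        msg <- c(msg, "ecReference must be a single value > 0")
    if (is.null(names(object@ec)) && length(object@ec))
        msg <- c(msg, "ec must be named by compound_id")
    ok <- is.na(object@ec) | object@ec > 0
    if (!all(ok))
        msg <- c(msg, "effect concentrations must be > 0 (NA = inactive)")
    rc <- object@referenceCompound
    if (rc %in% names(object@ec)) {
        ecr <- object@ec[[rc]]
        if (!is.na(ecr) && abs(log(ecr / object@ecReference)) > 1e-8)
            msg <- c(msg, "reference compound's ec must equal ecReference")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Partition-conversion policy
#'
#' Governs which lipid/PDMS partition coefficient is used when converting
#' silicone-based to lipid-based concentrations: the compound's
#' experimental value when available (and `useExperimentalFirst`), else a
#' study-wide fallback mean (`fallbackK`, default 23, the arithmetic mean
#' of the experimentally determined coefficients of the detected
#' compounds). `excludeFromMean` lists compounds (e.g. the HCH isomers)
#' left out when recomputing the fallback from data.
#'
#' @export
setClass("PartitionPolicy",
         representation(fallbackK = "numeric",
                        useExperimentalFirst = "logical",
                        excludeFromMean = "character"),
         prototype(fallbackK = 23,
                   useExperimentalFirst = TRUE,
                   excludeFromMean = character()))

setValidity("PartitionPolicy", function(object) {
    if (length(object@fallbackK) != 1L ||
        (!is.na(object@fallbackK) && object@fallbackK <= 0))
        return("fallbackK must be a single value > 0 (or NA to disable)")
    TRUE
})

#' @rdname PartitionPolicy-class
#' @param fallbackK fallback mean lipid/PDMS partition coefficient
#'   (default 23); `NA` disables the fallback, making a missing
#'   experimental value an error.
#' @param useExperimentalFirst prefer experimental per-compound values.
#' @param excludeFromMean compound names excluded when recomputing the
#'   fallback mean from data.
#' @export
PartitionPolicy <- function(fallbackK = 23, useExperimentalFirst = TRUE,
                            excludeFromMean = character()) {
    new("PartitionPolicy", fallbackK = as.numeric(fallbackK),
        useExperimentalFirst = useExperimentalFirst,
        excludeFromMean = excludeFromMean)
}

#' Volatility domain rule for bioassay capture
#'
#' Compounds with a bioassay-medium/air partition coefficient K_medium/air
#' below `thresholdKMediumAir` (default 1e4) evaporate from the test wells
#' and cannot be captured by the in vitro assays; they are excluded from
#' predicted mixture effects and accounted as a separate burden fraction.
#'
#' @export
setClass("VolatilityRule",
         representation(thresholdKMediumAir = "numeric"),
         prototype(thresholdKMediumAir = 1e4))

setValidity("VolatilityRule", function(object) {
    if (length(object@thresholdKMediumAir) != 1L ||
        is.na(object@thresholdKMediumAir) || object@thresholdKMediumAir <= 0)
        return("thresholdKMediumAir must be a single value > 0")
    TRUE
})

#' @rdname VolatilityRule-class
#' @param thresholdKMediumAir the K_medium/air cutoff (default 1e4).
#' @export
VolatilityRule <- function(thresholdKMediumAir = 1e4) {
    new("VolatilityRule",
        thresholdKMediumAir = as.numeric(thresholdKMediumAir))
}

#' Iceberg modeling results
#'
#' A `DataFrame` subclass with one row per extract-by-assay-by-endpoint:
#' measured (`beq_bio` / `tu_bio`) and predicted (`beq_chem` / `tu_chem`)
#' mixture effect, the explained fraction in percent, and the
#' mass-fraction accounting of the detected burden over the classes
#' captured / no effect data / volatile (percent, summing to 100).
#'
#' @export
setClass("IcebergResult", contains = "DFrame")

setValidity("IcebergResult", function(object) {
    req <- c("sample_id", "assay", "endpoint", "predicted", "measured",
             "explained_pct", "fraction_captured_pct",
             "fraction_no_effect_data_pct", "fraction_volatile_pct")
    missing <- setdiff(req, colnames(object))
    if (length(missing))
        return(paste("missing required column(s):",
                     paste(missing, collapse = ", ")))
    fr <- cbind(object$fraction_captured_pct,
                object$fraction_no_effect_data_pct,
                object$fraction_volatile_pct)
    if (any(fr < -1e-9, na.rm = TRUE))
        return("burden fractions must be >= 0")
    tot <- rowSums(fr)
    if (any(abs(tot - 100) > 1e-9, na.rm = TRUE))
        return("burden fractions must sum to 100")
    TRUE
})

#' Result of a ratio paired t-test
#'
#' Geometric-mean ratio of paired concentrations with its 95% confidence
#' interval and two-sided p-value, computed on the paired differences of
#' natural-log concentrations. `degenerate` flags zero log-ratio variance
#' (p and CI not meaningful); with fewer than two pairs only the point
#' estimate is defined.
#'
#' @export
setClass("RatioTestResult",
         representation(label = "character",
                        nPairs = "integer",
                        gmRatio = "numeric",
                        ciLow = "numeric",
                        ciHigh = "numeric",
                        pValue = "numeric",
                        significant = "logical",
                        degenerate = "logical"))

setValidity("RatioTestResult", function(object) {
    if (object@nPairs < 1L) return("nPairs must be >= 1")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        !(object@ciLow <= object@gmRatio + 1e-12 &&
          object@gmRatio <= object@ciHigh + 1e-12))
        return("confidence interval must bracket the geometric mean ratio")
    TRUE
})

## Column replacement on the annotated-DataFrame subclasses: modify as a
## plain DFrame, then restore the subclass (SimpleList's default method
## would otherwise try to wrap the value in the subclass itself).
.replaceColumn <- function(x, i, value, klass) {
    y <- as(x, "DFrame")
    y[[i]] <- value
    as(y, klass)
}

#' @describeIn CompoundRegistry-class column replacement.
#' @param x,i,j,...,value see [S4Vectors::DataFrame].
#' @export
setMethod("[[<-", "CompoundRegistry", function(x, i, j, ..., value)
    .replaceColumn(x, i, value, "CompoundRegistry"))

#' @describeIn SampleTable-class column replacement.
#' @param x,i,j,...,value see [S4Vectors::DataFrame].
#' @export
setMethod("[[<-", "SampleTable", function(x, i, j, ..., value)
    .replaceColumn(x, i, value, "SampleTable"))

#' @describeIn BioassayPanel-class column replacement.
#' @param x,i,j,...,value see [S4Vectors::DataFrame].
#' @export
setMethod("[[<-", "BioassayPanel", function(x, i, j, ..., value)
    .replaceColumn(x, i, value, "BioassayPanel"))

#' @describeIn IcebergResult-class column replacement.
#' @param x,i,j,...,value see [S4Vectors::DataFrame].
#' @export
setMethod("[[<-", "IcebergResult", function(x, i, j, ..., value)
    .replaceColumn(x, i, value, "IcebergResult"))
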