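#' Construct a ConcentrationTable
#'
#' @param conc numeric matrix of c_PDMS values (pg analyte / mg PDMS),
#'   compounds in rows and samples in columns; `NA` for nondetects.
#' @param status character matrix of the same shape with entries
#'   `"detected"`, `"nondetect"` or `"above_calibration"`. If missing, it
#'   is derived from `conc` (`NA` -> nondetect, else detected).
#' @param registry a [CompoundRegistry] whose `compound_id`s match
#'   `rownames(conc)`.
#' @param samples a [SampleTable] whose `sample_id`s match
#'   `colnames(conc)`.
#'
#' @return a validated [ConcentrationTable-class] object.
#' @examples
#' reg <- DataFrame(compound_id = c("a", "b"), name = c("A", "B"),
#'                  group = c("PCB", "PAH"), molar_mass_g_mol = c(300, 200),
#'                  mdl_pg_mg = c(1, 1))
#' smp <- DataFrame(sample_id = "s1", animal_id = "x1",
#'                  species = "harbor_porpoise", organ = "liver",
#'                  lipid_fraction = 0.05, pdms_mass_mg = 100,
#'                  lipid_uptake_fraction = 0.008)
#' conc <- matrix(c(10, NA), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' ConcentrationTable(conc, registry = as(reg, "CompoundRegistry"),
#'                    samples = as(smp, "SampleTable"))
#' @export
ConcentrationTable <- function(conc, status = NULL, registry, samples) {
    if (!is.matrix(conc) || !is.numeric(conc))
        stop("'conc' must be a numeric matrix")
    if (is.null(status)) {
        status <- matrix(ifelse(is.na(conc), "nondetect", "detected"),
                         nrow(conc), ncol(conc), dimnames = dimnames(conc))
    }
    registry <- as(registry, "CompoundRegistry")
    samples <- as(samples, "SampleTable")
    if (!identical(rownames(conc), as.character(registry$compound_id)))
        stop("rownames(conc) must equal registry compound_id, in order")
    if (!identical(colnames(conc), as.character(samples$sample_id)))
        stop("colnames(conc) must equal sample_id, in order")
    se <- SummarizedExperiment(
        assays = list(conc = conc, status = status),
        rowData = registry, colData = samples)
    rownames(se) <- registry$compound_id
    colnames(se) <- samples$sample_id
    out <- new("ConcentrationTable", se)
    metadata(out)$pipeline <- character()
    validObject(out)
    out
}

#' @describeIn ConcentrationTable the concentration assay
#'   (pg/mg PDMS; `NA` = nondetect).
#' @param x,object a `ConcentrationTable`.
#' @export
concMatrix <- function(x) assay(x, "conc")

#' @describeIn ConcentrationTable the detection-status assay.
#' @export
statusMatrix <- function(x) assay(x, "status")

#' @describeIn ConcentrationTable logical matrix, `TRUE` where the entry
#'   carries a quantified value (detected or above calibration).
#' @export
isDetected <- function(x) statusMatrix(x) != "nondetect"

#' @describeIn ConcentrationTable the compound registry (row metadata).
#' @export
compoundData <- function(x) as(rowData(x), "CompoundRegistry")

#' @describeIn ConcentrationTable the sample annotation (column metadata).
#' @export
sampleData <- function(x) as(as(colData(x), "DFrame"), "SampleTable")

.markStage <- function(x, stage) {
    metadata(x)$pipeline <- unique(c(metadata(x)$pipeline, stage))
    x
}

#' @describeIn ConcentrationTable pipeline stages already applied
#'   (subset of `"blank_subtracted"`, `"lipid_corrected"`, `"censored"`).
#' @export
pipelineStages <- function(x) metadata(x)$pipeline

setMethod("show", "ConcentrationTable", function(object) {
    callNextMethod()
    st <- statusMatrix(object)
    n <- length(st)
    cat(sprintf("detected: %d/%d entries (%.1f%%), above calibration: %d\n",
                sum(st != "nondetect"), n,
                100 * sum(st != "nondetect") / max(n, 1L),
                sum(st == "above_calibration")))
    stages <- pipelineStages(object)
    cat("pipeline:", if (length(stages)) paste(stages, collapse = " -> ")
        else "(raw)", "\n")
})

setMethod("show", "RatioTestResult", function(object) {
    cat(sprintf("ratio paired t-test [%s]: GM ratio %.3g (95%% CI %.3g-%.3g), p = %.3g, n = %d%s\n",
                object@label, object@gmRatio, object@ciLow, object@ciHigh,
                object@pValue, object@nPairs,
                if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "EffectDataset", function(object) {
    cat(sprintf("EffectDataset %s/%s: reference %s (EC %.3g mol/L), %d compounds with effect data (%d active)\n",
                object@assay, object@endpoint, object@referenceCompound,
                object@ecReference, length(object@ec),
                sum(!is.na(object@ec))))
})
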