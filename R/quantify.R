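## Raw-quantification post-processing. The canonical pipeline order is
## blank subtraction -> lipid-uptake correction -> MDL censoring; the end
## state is idempotent (re-censoring a censored table is a no-op).

#' @importFrom stats qt sd
NULL

#' Method detection limit from spiked replicates
#'
#' Computes the MDL as the Student-t quantile times the sample standard
#' deviation of replicate low-level spike measurements, following the
#' US EPA replicate-spike procedure. The default uses the two-tailed 99%
#' interval, i.e. the t quantile at cumulative probability 0.995 with
#' n - 1 degrees of freedom; `method = "epa_one_tailed"` selects the
#' classic 40 CFR 136 Appendix B one-tailed 99% variant (quantile at
#' 0.99).
#'
#' @param replicates numeric vector of replicate spike measurements
#'   (pg/mg PDMS), at least two, all non-negative.
#' @param confidence confidence level of the interval (default 0.99).
#' @param method `"two_tailed"` (default) or `"epa_one_tailed"`.
#' @return the MDL in pg/mg PDMS; strictly positive unless the replicate
#'   standard deviation is zero.
#' @examples
#' computeMDL(c(9, 10, 11, 9.5, 10.5, 10, 9.8, 10.2))
#' @export
computeMDL <- function(replicates, confidence = 0.99,
                       method = c("two_tailed", "epa_one_tailed")) {
    method <- match.arg(method)
    replicates <- as.numeric(replicates)
    n <- length(replicates)
    if (n < 2L)
        stop("insufficient replicates: MDL needs >= 2, got ", n)
    if (any(is.na(replicates) | replicates < 0))
        stop("replicates must be non-negative and non-missing")
    p <- if (method == "two_tailed") 1 - (1 - confidence) / 2 else confidence
    qt(p, df = n - 1L) * sd(replicates)
}

#' Subtract procedural blanks
#'
#' Reduces every quantified value by the arithmetic mean of the
#' procedural blanks for that compound. Compounds without blank entries
#' are unchanged; values driven to zero or below become nondetects.
#'
#' @param x a [ConcentrationTable-class].
#' @param blanks named list, `compound_id -> numeric vector` of
#'   procedural-blank concentrations (pg/mg PDMS, non-negative). May be
#'   empty.
#' @return the blank-corrected [ConcentrationTable-class].
#' @export
subtractBlanks <- function(x, blanks = list()) {
    stopifnot(is(x, "ConcentrationTable"), is.list(blanks))
    unknown <- setdiff(names(blanks), rownames(x))
    if (length(unknown))
        stop("blanks reference unknown compound_id: ",
             paste(unknown, collapse = ", "))
    cc <- concMatrix(x)
    st <- statusMatrix(x)
    for (cid in names(blanks)) {
        b <- as.numeric(blanks[[cid]])
        if (!length(b)) next
        if (any(is.na(b) | b < 0))
            stop("blank values must be non-negative for ", cid)
        cc[cid, ] <- cc[cid, ] - mean(b)
    }
    gone <- !is.na(cc) & cc <= 0
    cc[gone] <- NA_real_
    st[gone] <- "nondetect"
    assay(x, "conc") <- cc
    assay(x, "status") <- st
    .markStage(x, "blank_subtracted")
}

#' Correct an analyte mass for lipid co-extraction (scalar form)
#'
#' During in-tissue passive sampling the polymer gains weight by lipid
#' uptake; part of the extracted analyte resided in that co-extracted
#' lipid rather than in the PDMS itself. The corrected silicone-based
#' concentration follows from the two-phase mass balance
#' `c_PDMS * (m_PDMS + K_lipid/PDMS * m_lipid) = analyte mass`, which
#' reduces to the naive `mass / m_PDMS` when the uptake is zero.
#'
#' @param analyteMass extracted analyte mass, pg.
#' @param pdmsMass PDMS sheet mass, mg (> 0).
#' @param lipidMass co-extracted lipid mass, mg (>= 0).
#' @param k the compound's lipid/PDMS partition coefficient.
#' @return c_PDMS in pg/mg PDMS.
#' @examples
#' correctLipidUptake(1000, 100, 1, 23)  # 1000/123
#' @export
correctLipidUptake <- function(analyteMass, pdmsMass, lipidMass, k) {
    if (any(pdmsMass <= 0)) stop("pdms mass must be > 0")
    if (any(lipidMass < 0)) stop("lipid mass must be >= 0")
    if (any(k <= 0)) stop("partition coefficient must be > 0")
    analyteMass / (pdmsMass + k * lipidMass)
}

#' Apply lipid-uptake correction to a whole table
#'
#' Rescales every quantified value by `1 / (1 + K_i * u_j)` where `u_j`
#' is sample j's lipid uptake per unit PDMS mass (g lipid / g PDMS) and
#' `K_i` the compound's lipid/PDMS partition coefficient (experimental
#' where available, else the policy fallback). This is the table form of
#' [correctLipidUptake()]: the naive `mass / m_PDMS` value is replaced by
#' the two-phase mass-balance value `mass / (m_PDMS + K * m_lipid)`.
#'
#' @param x a [ConcentrationTable-class] of naive (PDMS-mass-only)
#'   concentrations.
#' @param policy a [PartitionPolicy-class] supplying fallback partition
#'   coefficients.
#' @return the corrected [ConcentrationTable-class].
#' @export
applyLipidUptakeCorrection <- function(x, policy = PartitionPolicy()) {
    stopifnot(is(x, "ConcentrationTable"))
    k <- partitionK(compoundData(x), policy)
    u <- sampleData(x)$lipid_uptake_fraction
    cc <- concMatrix(x)
    factor <- 1 / (1 + outer(k, u))          # compounds x samples
    assay(x, "conc") <- cc * factor
    .markStage(x, "lipid_corrected")
}

#' Censor a concentration table at the method detection limits
#'
#' Quantified values strictly below the compound's MDL become
#' nondetects; a value exactly at the MDL stays detected. Censoring is
#' idempotent and monotone: raising any MDL can only reduce that
#' compound's detection count.
#'
#' @param x a [ConcentrationTable-class].
#' @param mdl optional named numeric vector of MDLs (pg/mg) overriding
#'   the registry column `mdl_pg_mg`.
#' @return the censored [ConcentrationTable-class].
#' @export
censorTable <- function(x, mdl = NULL) {
    stopifnot(is(x, "ConcentrationTable"))
    if (is.null(mdl)) {
        mdl <- compoundData(x)$mdl_pg_mg
        names(mdl) <- rownames(x)
    } else {
        missing <- setdiff(rownames(x), names(mdl))
        if (length(missing))
            stop("no MDL provided for: ", paste(missing, collapse = ", "))
        mdl <- mdl[rownames(x)]
    }
    cc <- concMatrix(x)
    st <- statusMatrix(x)
    below <- !is.na(cc) & cc < mdl           # column-recycled by row
    cc[below] <- NA_real_
    st[below] <- "nondetect"
    assay(x, "conc") <- cc
    assay(x, "status") <- st
    .markStage(x, "censored")
}

#' Run the full quantification pipeline
#'
#' Convenience wrapper applying, in the fixed order, blank subtraction,
#' lipid-uptake correction and MDL censoring.
#'
#' @param x a raw [ConcentrationTable-class] of naive concentrations.
#' @param blanks named list of procedural-blank vectors (see
#'   [subtractBlanks()]).
#' @param policy a [PartitionPolicy-class].
#' @param correctLipid set `FALSE` to skip the lipid-uptake correction
#'   (sensitivity analysis).
#' @return a censored, analysis-ready [ConcentrationTable-class].
#' @export
quantifyPipeline <- function(x, blanks = list(), policy = PartitionPolicy(),
                             correctLipid = TRUE) {
    x <- subtractBlanks(x, blanks)
    if (correctLipid) x <- applyLipidUptakeCorrection(x, policy)
    censorTable(x)
}
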