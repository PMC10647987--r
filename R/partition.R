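## Equilibrium-partitioning conversions between silicone-, lipid- and
## wet-weight-based concentration scales. Numerically: 1 pg/mg PDMS times
## K gives pg/mg lipid; lipid-based burdens are reported in mg/kg lipid
## (1 pg/mg = 1e-3 mg/kg).

#' Partition coefficients for a registry under a policy
#'
#' Resolves the lipid/PDMS partition coefficient used for each compound:
#' the experimental value when available and `useExperimentalFirst` is
#' set, else the policy's fallback mean. With the fallback disabled
#' (`fallbackK = NA`), a compound without experimental value is an error.
#'
#' @param registry a [CompoundRegistry].
#' @param policy a [PartitionPolicy-class].
#' @return named numeric vector of K_lipid/PDMS per compound.
#' @export
partitionK <- function(registry, policy = PartitionPolicy()) {
    k_exp <- if ("k_lipid_pdms" %in% colnames(registry))
        registry$k_lipid_pdms else rep(NA_real_, nrow(registry))
    k <- if (policy@useExperimentalFirst)
        ifelse(is.na(k_exp), policy@fallbackK, k_exp)
    else rep(policy@fallbackK, nrow(registry))
    if (any(is.na(k))) {
        stop("missing partition coefficient (and fallback disabled) for: ",
             paste(registry$compound_id[is.na(k)], collapse = ", "))
    }
    names(k) <- registry$compound_id
    k
}

#' Convert silicone-based to equilibrium lipid-based concentrations
#'
#' `c_lipid,eq = K_lipid/PDMS x c_PDMS`: the lipid-normalized
#' concentration the tissue lipid holds at equilibrium with the measured
#' silicone phase. Output is in mg analyte per kg lipid (a c_PDMS of
#' 10 pg/mg with K = 23 gives 230 pg/mg lipid = 0.23 mg/kg lipid).
#'
#' @param cPdms numeric c_PDMS value(s), pg/mg PDMS, >= 0.
#' @param k lipid/PDMS partition coefficient(s), recycled against
#'   `cPdms`.
#' @return c_lipid,eq in mg/kg lipid.
#' @seealso [toLipidBasis()] for the whole-table version resolving K via
#'   a [PartitionPolicy-class].
#' @export
toLipid <- function(cPdms, k) {
    if (any(cPdms < 0, na.rm = TRUE)) stop("c_PDMS must be >= 0")
    if (any(k <= 0, na.rm = TRUE)) stop("K must be > 0")
    k * cPdms * 1e-3
}

#' Lipid-based concentration matrix for a study
#'
#' @param x a [ConcentrationTable-class].
#' @param policy a [PartitionPolicy-class].
#' @param nondetect value substituted for nondetects (default 0, the
#'   lower-bound convention used for sum burdens).
#' @return matrix of c_lipid,eq in mg/kg lipid, compounds x samples.
#' @export
toLipidBasis <- function(x, policy = PartitionPolicy(), nondetect = 0) {
    k <- partitionK(compoundData(x), policy)
    cc <- concMatrix(x)
    cc[is.na(cc)] <- nondetect
    k * cc * 1e-3
}

#' Convert lipid-based to wet-weight-based concentrations
#'
#' `c_ww = c_lipid x lipid fraction` of the tissue.
#'
#' @param cLipid concentration(s) in mg/kg lipid.
#' @param lipidFraction g lipid per g tissue, in \[0, 1\].
#' @return concentration(s) in mg/kg wet weight.
#' @export
toWetWeight <- function(cLipid, lipidFraction) {
    if (any(lipidFraction < 0 | lipidFraction > 1, na.rm = TRUE))
        stop("lipid fraction must lie in [0, 1]")
    cLipid * lipidFraction
}

#' Mean partition coefficient from experimental values
#'
#' The study-wide fallback K is the average of the experimentally
#' determined lipid/PDMS coefficients of the detected compounds,
#' excluding compounds named in the policy's exclusion list (the HCH
#' isomers in the motivating study). Arithmetic mean by default; a
#' geometric-mean option exists because partition coefficients are
#' log-distributed.
#'
#' @param k numeric vector of experimental K values (> 0), named by
#'   compound when an exclusion list is used.
#' @param exclude compound names to drop before averaging.
#' @param type `"arithmetic"` (default) or `"geometric"`.
#' @return the mean K.
#' @export
meanKExperimental <- function(k, exclude = character(),
                              type = c("arithmetic", "geometric")) {
    type <- match.arg(type)
    if (length(exclude))
        k <- k[!names(k) %in% exclude]
    k <- k[!is.na(k)]
    if (!length(k)) stop("no experimental partition coefficients to average")
    if (any(k <= 0)) stop("partition coefficients must be > 0")
    if (type == "arithmetic") mean(k) else exp(mean(log(k)))
}

#' Cross-check converted lipid concentrations against exhaustive extraction
#'
#' Compares equilibrium-converted lipid-based concentrations with paired
#' lipid-based concentrations from exhaustive solvent extraction of the
#' same tissue; pairs disagreeing by more than `factor`-fold in either
#' direction are flagged.
#'
#' @param cLipidEq converted c_lipid,eq values (mg/kg lipid, > 0).
#' @param cLipidExhaustive paired exhaustive-extraction values (mg/kg
#'   lipid, > 0).
#' @param factor agreement factor (default 3).
#' @return data.frame with the pairwise ratio (converted / exhaustive)
#'   and a logical `within_factor`.
#' @export
partitionConsistencyCheck <- function(cLipidEq, cLipidExhaustive,
                                      factor = 3) {
    stopifnot(length(cLipidEq) == length(cLipidExhaustive), factor >= 1)
    if (any(cLipidEq <= 0 | cLipidExhaustive <= 0, na.rm = TRUE))
        stop("consistency check needs positive paired concentrations")
    ratio <- cLipidEq / cLipidExhaustive
    data.frame(ratio = ratio,
               within_factor = ratio <= factor & ratio >= 1 / factor)
}
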