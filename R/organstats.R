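## Descriptive and inferential statistics over the censored concentration
## matrix: detection frequencies, geometric summaries of detected values,
## paired organ ratio tests on the log scale, substance-group profiles
## and effect-threshold exceedance. Sum burdens use the lower-bound
## convention (nondetects contribute zero).

#' @importFrom stats t.test
NULL

#' Per-compound detection frequencies
#'
#' @param x a [ConcentrationTable-class].
#' @return `DataFrame` with `compound_id`, `n_detected`, `n_samples` and
#'   `pct_detected`; compounds never detected are reported with 0.
#' @export
detectionFrequency <- function(x) {
    det <- unname(rowSums(isDetected(x)))
    DataFrame(compound_id = rownames(x),
              n_detected = as.integer(det),
              n_samples = ncol(x),
              pct_detected = 100 * det / ncol(x))
}

#' Geometric mean and geometric standard deviation
#'
#' `GM = exp(mean(ln x))`, `GSD = exp(sd(ln x))`, over detected values
#' only; any non-positive value is an error (censored values must be
#' removed, not zero-filled, before a geometric summary).
#'
#' @param values numeric vector of detected concentrations (> 0).
#' @return list with `gm`, `gsd` (NA for a single value) and `n`.
#' @examples
#' geoSummary(c(2, 4, 8))  # gm = 4
#' @export
geoSummary <- function(values) {
    values <- values[!is.na(values)]
    if (!length(values)) stop("no values for geometric summary")
    if (any(values <= 0))
        stop("geometric summary requires strictly positive values")
    lx <- log(values)
    list(gm = exp(mean(lx)),
         gsd = if (length(lx) > 1L) exp(sd(lx)) else NA_real_,
         n = length(values))
}

#' Ratio paired t-test on log-transformed concentrations
#'
#' Tests whether paired concentrations differ by a constant factor: a
#' paired t-test on `ln(numerator) - ln(denominator)`. The geometric
#' mean ratio is `exp(mean difference)` and its 95% confidence interval
#' `exp(mean +- t(0.975, n-1) * SE)`. Pairs with a nondetect or
#' non-positive member are dropped (no imputation by default). With a
#' single pair only the point estimate is returned; with zero log-ratio
#' variance the result is flagged degenerate.
#'
#' @param numerator,denominator paired positive concentrations (e.g.
#'   liver and blubber c_PDMS of the same animals); `NA` encodes
#'   nondetect.
#' @param label descriptive label carried into the result.
#' @param alpha significance level (default 0.05).
#' @return a [RatioTestResult-class].
#' @export
ratioPairedTTest <- function(numerator, denominator, label = "",
                             alpha = 0.05) {
    stopifnot(length(numerator) == length(denominator))
    keep <- !is.na(numerator) & !is.na(denominator) &
        numerator > 0 & denominator > 0
    num <- numerator[keep]
    den <- denominator[keep]
    n <- length(num)
    if (n < 1L) stop("no complete detected pairs")
    d <- log(num) - log(den)
    gm <- exp(mean(d))
    if (n < 2L) {
        return(new("RatioTestResult", label = label, nPairs = 1L,
                   gmRatio = gm, ciLow = NA_real_, ciHigh = NA_real_,
                   pValue = NA_real_, significant = NA,
                   degenerate = FALSE))
    }
    tt <- if (sd(d) == 0) NULL
          else tryCatch(t.test(d, conf.level = 0.95),
                        error = function(e) NULL)
    if (is.null(tt)) {       # zero (or numerically zero) log-ratio variance
        return(new("RatioTestResult", label = label, nPairs = as.integer(n),
                   gmRatio = gm, ciLow = gm, ciHigh = gm,
                   pValue = NA_real_, significant = NA, degenerate = TRUE))
    }
    ci <- exp(as.numeric(tt$conf.int))
    new("RatioTestResult", label = label, nPairs = as.integer(n),
        gmRatio = gm, ciLow = ci[1L], ciHigh = ci[2L],
        pValue = tt$p.value, significant = tt$p.value < alpha,
        degenerate = FALSE)
}

#' Paired organ concentration ratios across animals
#'
#' Builds the per-animal paired concentrations of two organs and runs
#' the ratio paired t-test, either per compound or summed over a
#' compound set (lower-bound sums; an animal enters a summed test when
#' both organ sums are positive).
#'
#' @param x a [ConcentrationTable-class].
#' @param compounds compound ids: a single id gives a per-compound test
#'   on detected pairs; several ids give a test on the summed burden.
#' @param numeratorOrgan,denominatorOrgan organ names (defaults
#'   liver / blubber, the chemical-activity ratio of the motivating
#'   design).
#' @param label result label; defaults to the compound set.
#' @return a [RatioTestResult-class].
#' @export
organRatioTest <- function(x, compounds,
                           numeratorOrgan = "liver",
                           denominatorOrgan = "blubber",
                           label = NULL) {
    smp <- sampleData(x)
    cc <- concMatrix(x)
    missing <- setdiff(compounds, rownames(cc))
    if (length(missing))
        stop("unknown compound_id: ", paste(missing, collapse = ", "))
    animals <- unique(smp$animal_id)
    val <- function(organ, a) {
        sel <- smp$sample_id[smp$animal_id == a & smp$organ == organ]
        if (!length(sel)) return(NA_real_)
        v <- cc[compounds, sel[1L], drop = TRUE]
        if (length(compounds) == 1L) v
        else { s <- sum(v, na.rm = TRUE); if (s > 0) s else NA_real_ }
    }
    num <- vapply(animals, function(a) val(numeratorOrgan, a), numeric(1))
    den <- vapply(animals, function(a) val(denominatorOrgan, a), numeric(1))
    if (is.null(label))
        label <- if (length(compounds) == 1L) compounds
                 else sprintf("sum of %d compounds (%s/%s)",
                              length(compounds), numeratorOrgan,
                              denominatorOrgan)
    ratioPairedTTest(num, den, label = label)
}

#' Substance-group profile of each extract
#'
#' Percentage of each sample's detected burden contributed by each
#' compound group, on the pg/mg (mass) scale by default.
#'
#' @param x a [ConcentrationTable-class].
#' @param basis `"mass"` (default) or `"molar"`.
#' @return matrix samples x groups, rows summing to 100; samples with
#'   no detected compound are an error.
#' @export
groupProfile <- function(x, basis = c("mass", "molar")) {
    basis <- match.arg(basis)
    cc <- concMatrix(x)
    cc[is.na(cc)] <- 0
    if (basis == "molar")
        cc <- cc / compoundData(x)$molar_mass_g_mol
    grp <- factor(compoundData(x)$group, levels = .COMPOUND_GROUPS)
    tot <- colSums(cc)
    if (any(tot <= 0))
        stop("sample(s) without detected compounds: ",
             paste(colnames(cc)[tot <= 0], collapse = ", "))
    byGroup <- do.call(rbind, lapply(levels(grp), function(g)
        colSums(cc[grp == g, , drop = FALSE])))
    rownames(byGroup) <- levels(grp)
    t(byGroup) / tot * 100
}

#' Lower-bound sum burden over a compound set
#'
#' @param x a [ConcentrationTable-class].
#' @param compounds compound ids to sum.
#' @param basis `"pdms"` (pg/mg), `"lipid"` (mg/kg lipid) or `"wet"`
#'   (mg/kg wet weight).
#' @param policy a [PartitionPolicy-class] for the lipid conversion.
#' @return named numeric vector over samples; nondetects count as zero.
#' @export
sumBurden <- function(x, compounds, basis = c("pdms", "lipid", "wet"),
                      policy = PartitionPolicy()) {
    basis <- match.arg(basis)
    missing <- setdiff(compounds, rownames(x))
    if (length(missing))
        stop("unknown compound_id: ", paste(missing, collapse = ", "))
    m <- switch(basis,
                pdms = { cc <- concMatrix(x); cc[is.na(cc)] <- 0; cc },
                lipid = toLipidBasis(x, policy),
                wet = {
                    lf <- sampleData(x)$lipid_fraction
                    if (anyNA(lf))
                        stop("wet-weight basis needs lipid fractions")
                    t(t(toLipidBasis(x, policy)) * lf)
                })
    colSums(m[compounds, , drop = FALSE])
}

#' Effect-threshold rules
#'
#' Builds the rule set used for threshold assessment. The defaults are
#' the three commonly used sum-PCB thresholds in marine-mammal tissue --
#' (I) 9.0 mg/kg lipid for the general onset of physiological impacts,
#' (II) 11.0 mg/kg lipid for expected reproductive failure in harbor
#' porpoises and (III) 41.0 mg/kg lipid for profound reproductive
#' impairment -- applied here to the study's PCB congener sum, plus the
#' 1 mg/kg wet-weight toxicity threshold for the DDX sum (4,4'-DDE +
#' 4,4'-DDD + 4,4'-DDT).
#'
#' @param registry a [CompoundRegistry]; PCB rules take all `group ==
#'   "PCB"` compounds, the DDX rule the compounds named 4,4'-DDE/DDD/DDT.
#' @return `DataFrame` with columns `name`, `basis`, `value_mg_kg` and a
#'   list column `analytes`.
#' @export
defaultThresholdRules <- function(registry) {
    pcb <- registry$compound_id[registry$group == "PCB"]
    ddx <- registry$compound_id[registry$name %in%
                                c("4,4'-DDE", "4,4'-DDD", "4,4'-DDT")]
    DataFrame(name = c("PCB_I_onset", "PCB_II_reproduction",
                       "PCB_III_profound", "DDX_toxicity"),
              basis = c("lipid", "lipid", "lipid", "wet_weight"),
              value_mg_kg = c(9.0, 11.0, 41.0, 1.0),
              analytes = I(list(pcb, pcb, pcb, ddx)))
}

#' Assess effect-threshold exceedance
#'
#' For each sample and rule, sums the rule's analyte set on the rule's
#' basis (lipid- or wet-weight-normalized, mg/kg) and tests strict
#' exceedance (`burden > threshold`; a burden exactly at the threshold
#' does not transgress it).
#'
#' @param x a [ConcentrationTable-class].
#' @param rules a rule table as from [defaultThresholdRules()].
#' @param policy a [PartitionPolicy-class].
#' @return list with `burden` (samples x rules, mg/kg on each rule's
#'   basis), logical `exceeded` of the same shape, per-rule sample
#'   counts `n_samples_exceeding` and per-rule counts of animals with an
#'   exceedance in at least one organ, `n_animals_exceeding`.
#' @export
assessThresholds <- function(x, rules = defaultThresholdRules(compoundData(x)),
                             policy = PartitionPolicy()) {
    smp <- sampleData(x)
    burden <- sapply(seq_len(nrow(rules)), function(i) {
        basis <- if (rules$basis[i] == "lipid") "lipid" else "wet"
        sumBurden(x, rules$analytes[[i]], basis = basis, policy = policy)
    })
    burden <- matrix(burden, nrow = ncol(x),
                     dimnames = list(colnames(x), rules$name))
    exceeded <- sweep(burden, 2L, rules$value_mg_kg, `>`)
    nAnimals <- apply(exceeded, 2L, function(e)
        length(unique(smp$animal_id[e])))
    list(burden = burden, exceeded = exceeded,
         n_samples_exceeding = colSums(exceeded),
         n_animals_exceeding = nAnimals)
}
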