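## Concentration-addition iceberg modeling. Predicted mixture effects are
## built from quantified chemicals as bioanalytical equivalents
## (BEQ_chem = sum REP_i * c_i, REP_i = EC_ref / EC_i) or toxic units
## (TU_chem = sum c_i / IC_i); measured effects come from whole-extract
## bioassay EC/IC values (BEQ_bio = EC_ref / EC_extract,
## TU_bio = 1 / IC_extract). The explained fraction is the ratio of
## predicted to measured effect, the visible tip of the iceberg.

## pg analyte / mg PDMS -> mol analyte / kg PDMS
.molPerKg <- function(cPdms, molarMass) cPdms * 1e-6 / molarMass

#' Build an effect dataset from registry columns
#'
#' Collects the per-compound effect concentrations for one assay
#' endpoint from the registry columns `ec_<assay>_mol_l` (activation) or
#' `ic_<assay>_mol_l` (cytotoxicity), restricted to compounds flagged
#' `effect_tested`. Compounds tested but without a concentration (`NA`)
#' are retained as measured-inactive.
#'
#' @param registry a [CompoundRegistry].
#' @param assay one of `"ahr_calux"`, `"arec32"`, `"pparg_bla"`.
#' @param endpoint `"activation"` or `"cytotoxicity"`.
#' @param referenceCompound id of the assay's reference chemical (need
#'   not be a registry analyte, e.g. rosiglitazone for PPARg).
#' @param ecReference the reference chemical's effect concentration in
#'   the assay, mol/L. Defaults to the reference compound's own registry
#'   entry when it is an analyte.
#' @return an [EffectDataset-class].
#' @export
effectDatasetFromRegistry <- function(registry, assay,
                                      endpoint = c("activation",
                                                   "cytotoxicity"),
                                      referenceCompound,
                                      ecReference = NULL) {
    endpoint <- match.arg(endpoint)
    col <- sprintf("%s_%s_mol_l",
                   if (endpoint == "activation") "ec" else "ic", assay)
    if (!col %in% colnames(registry))
        stop("registry has no effect column ", col)
    tested <- if ("effect_tested" %in% colnames(registry))
        which(registry$effect_tested %in% TRUE) else seq_len(nrow(registry))
    ec <- registry[[col]][tested]
    names(ec) <- registry$compound_id[tested]
    if (is.null(ecReference)) {
        if (!referenceCompound %in% names(ec) ||
            is.na(ec[[referenceCompound]]))
            stop("ecReference not given and reference compound '",
                 referenceCompound, "' has no ", col, " entry")
        ecReference <- ec[[referenceCompound]]
    }
    new("EffectDataset", assay = assay, endpoint = endpoint,
        referenceCompound = referenceCompound,
        ecReference = as.numeric(ecReference), ec = ec)
}

#' Classify compounds by bioassay capture domain
#'
#' Each compound is `volatile_excluded` when its bioassay-medium/air
#' partition coefficient K_medium/air lies below the rule threshold
#' (such chemicals evaporate from the test wells), else `captured` when
#' effect data exist for the assay battery (including compounds measured
#' inactive), else `no_effect_data`. Compounds without a K_medium/air
#' value are treated as non-volatile with a warning.
#'
#' @param registry a [CompoundRegistry] (needs `log_k_medium_air` and
#'   `effect_tested` columns).
#' @param rule a [VolatilityRule-class].
#' @return named character vector over compounds with values
#'   `"captured"`, `"no_effect_data"`, `"volatile_excluded"`.
#' @export
classifyCompounds <- function(registry, rule = VolatilityRule()) {
    logK <- if ("log_k_medium_air" %in% colnames(registry))
        registry$log_k_medium_air else rep(NA_real_, nrow(registry))
    if (anyNA(logK))
        warning("missing K_medium/air for ",
                sum(is.na(logK)), " compound(s); treated as non-volatile")
    volatile <- !is.na(logK) & 10^logK < rule@thresholdKMediumAir
    tested <- if ("effect_tested" %in% colnames(registry))
        registry$effect_tested %in% TRUE
    else rep(FALSE, nrow(registry))
    cls <- ifelse(volatile, "volatile_excluded",
                  ifelse(tested, "captured", "no_effect_data"))
    names(cls) <- registry$compound_id
    cls
}

#' Measured bioanalytical equivalent concentration of an extract
#'
#' `BEQ_bio = EC_reference / EC_extract`: the amount of reference
#' chemical per kg of PDMS-equivalent extract that would produce the
#' observed benchmark activation.
#'
#' @param ecReference reference chemical's effect concentration, mol/L.
#' @param ecExtract extract concentration causing the benchmark effect,
#'   kg PDMS / L.
#' @return BEQ_bio in mol reference / kg PDMS.
#' @export
beqBio <- function(ecReference, ecExtract) {
    if (any(ecReference <= 0) || any(ecExtract <= 0))
        stop("effect concentrations must be > 0")
    ecReference / ecExtract
}

#' Measured toxic units of an extract
#'
#' `TU_bio = 1 / IC_extract` with the extract's cytotoxic concentration
#' in kg PDMS / L.
#'
#' @param icExtract extract concentration causing the benchmark
#'   cytotoxicity, kg PDMS / L.
#' @return TU_bio in L / kg PDMS.
#' @export
tuBio <- function(icExtract) {
    if (any(icExtract <= 0)) stop("IC_extract must be > 0")
    1 / icExtract
}

.chemSum <- function(cPdms, effects, registry) {
    if (any(cPdms < 0, na.rm = TRUE))
        stop("concentrations must be >= 0")
    cPdms <- cPdms[!is.na(cPdms)]
    ids <- intersect(names(cPdms), names(effects@ec))
    mm <- registry$molar_mass_g_mol[match(ids, registry$compound_id)]
    if (anyNA(mm))
        stop("molar mass missing for: ",
             paste(ids[is.na(mm)], collapse = ", "))
    cMol <- .molPerKg(cPdms[ids], mm)
    ec <- effects@ec[ids]
    pot <- ifelse(is.na(ec), 0, 1 / ec)      # inactive -> zero potency
    contrib <- if (effects@endpoint == "activation")
        effects@ecReference * pot * cMol     # REP_i * c_i
    else pot * cMol                          # c_i / IC_i
    names(contrib) <- ids
    list(total = sum(contrib), contributions = contrib)
}

#' Predicted bioanalytical equivalent concentration from chemical analysis
#'
#' Concentration-addition prediction `BEQ_chem = sum_i REP_i * c_i` over
#' the detected compounds with effect data in the assay, where
#' `REP_i = EC_reference / EC_i` is the relative effect potency and
#' `c_i` the compound's molar concentration per kg PDMS. Compounds
#' measured inactive contribute zero.
#'
#' @param cPdms named numeric vector of detected c_PDMS values for one
#'   extract (pg/mg PDMS), named by `compound_id`; `NA`s are ignored.
#' @param effects an activation [EffectDataset-class].
#' @param registry a [CompoundRegistry] supplying molar masses.
#' @return list with `total` (mol reference / kg PDMS) and the named
#'   per-compound `contributions` summing to it.
#' @export
beqChem <- function(cPdms, effects, registry) {
    stopifnot(is(effects, "EffectDataset"))
    if (effects@endpoint != "activation")
        stop("beqChem needs an activation effect dataset")
    .chemSum(cPdms, effects, registry)
}

#' Predicted toxic units from chemical analysis
#'
#' `TU_chem = sum_i c_i / IC_i` over detected compounds with
#' cytotoxicity data (c_i in mol/kg PDMS, IC_i in mol/L).
#'
#' @inheritParams beqChem
#' @param effects a cytotoxicity [EffectDataset-class].
#' @return list with `total` (L bioassay / kg PDMS) and per-compound
#'   `contributions`.
#' @export
tuChem <- function(cPdms, effects, registry) {
    stopifnot(is(effects, "EffectDataset"))
    if (effects@endpoint != "cytotoxicity")
        stop("tuChem needs a cytotoxicity effect dataset")
    .chemSum(cPdms, effects, registry)
}

#' Fraction of the measured effect explained by quantified chemicals
#'
#' `100 x predicted / measured`; values above 100% are possible and are
#' reported as-is.
#'
#' @param predicted BEQ_chem or TU_chem.
#' @param measured BEQ_bio or TU_bio (> 0).
#' @return percentage.
#' @export
explainedFraction <- function(predicted, measured) {
    if (any(measured <= 0))
        stop("measured effect must be > 0 for an explained fraction")
    if (any(predicted < 0)) stop("predicted effect must be >= 0")
    100 * predicted / measured
}

#' Burden accounting over bioassay-capture classes
#'
#' Splits one extract's detected burden into the shares attributable to
#' compounds whose effect could be captured by the assays, compounds
#' without effect data, and compounds too volatile for the test system.
#' Shares are concentration-weighted on the pg/mg scale by default; a
#' molar basis is available.
#'
#' @param cPdms named numeric vector of detected c_PDMS values (pg/mg)
#'   for one extract; `NA`s are ignored.
#' @param classification named classification from
#'   [classifyCompounds()].
#' @param registry a [CompoundRegistry]; needed for `basis = "molar"`.
#' @param basis `"mass"` (default) or `"molar"`.
#' @return named numeric: `captured`, `no_effect_data`,
#'   `volatile_excluded`, percentages summing to 100.
#' @export
fractionAccounting <- function(cPdms, classification, registry = NULL,
                               basis = c("mass", "molar")) {
    basis <- match.arg(basis)
    cPdms <- cPdms[!is.na(cPdms)]
    if (!length(cPdms) || sum(cPdms) <= 0)
        stop("no detected compounds: burden accounting undefined")
    missing <- setdiff(names(cPdms), names(classification))
    if (length(missing))
        stop("no classification for: ", paste(missing, collapse = ", "))
    w <- cPdms
    if (basis == "molar") {
        if (is.null(registry)) stop("molar basis needs the registry")
        mm <- registry$molar_mass_g_mol[match(names(w),
                                              registry$compound_id)]
        w <- w / mm
    }
    cls <- factor(classification[names(w)],
                  levels = c("captured", "no_effect_data",
                             "volatile_excluded"))
    shares <- vapply(split(w, cls), sum, numeric(1))
    100 * shares / sum(w)
}

#' Run iceberg modeling for a whole study
#'
#' For every bioassay measurement, predicts the mixture effect from the
#' extract's detected compounds (BEQ_chem for activation endpoints,
#' TU_chem for cytotoxicity), pairs it with the measured effect (BEQ_bio
#' / TU_bio), and reports the explained fraction together with the
#' burden accounting over capture classes. Rows whose extract contains
#' above-calibration values are flagged semi-quantitative.
#'
#' @param x a censored [ConcentrationTable-class].
#' @param effectsList list of [EffectDataset-class] objects covering the
#'   assay endpoints present in `bioassays`.
#' @param bioassays a [BioassayPanel].
#' @param rule a [VolatilityRule-class].
#' @param basis burden-accounting basis, `"mass"` or `"molar"`.
#' @return an [IcebergResult-class]; per-compound contribution maps are
#'   attached as `metadata(result)$contributions`, keyed
#'   `<sample>.<assay>.<endpoint>`.
#' @export
runIceberg <- function(x, effectsList, bioassays, rule = VolatilityRule(),
                       basis = "mass") {
    stopifnot(is(x, "ConcentrationTable"), is(bioassays, "BioassayPanel"))
    registry <- compoundData(x)
    classification <- classifyCompounds(registry, rule)
    cc <- concMatrix(x)
    st <- statusMatrix(x)
    keyOf <- function(e) paste(e@assay, e@endpoint, sep = ".")
    names(effectsList) <- vapply(effectsList, keyOf, character(1))

    n <- nrow(bioassays)
    pred <- meas <- expl <- frC <- frN <- frV <- rep(NA_real_, n)
    semi <- logical(n)
    contribs <- vector("list", n)
    for (i in seq_len(n)) {
        sid <- bioassays$sample_id[i]
        if (!sid %in% colnames(cc))
            stop("bioassay row references unknown sample_id: ", sid)
        key <- paste(bioassays$assay[i], bioassays$endpoint[i], sep = ".")
        eff <- effectsList[[key]]
        if (is.null(eff))
            stop("no effect dataset supplied for ", key)
        cs <- cc[, sid]
        names(cs) <- rownames(cc)
        chem <- if (eff@endpoint == "activation")
            beqChem(cs, eff, registry) else tuChem(cs, eff, registry)
        pred[i] <- chem$total
        meas[i] <- if (eff@endpoint == "activation")
            beqBio(bioassays$ec_reference_mol_l[i],
                   bioassays$ec_extract_kg_l[i])
        else tuBio(bioassays$ec_extract_kg_l[i])
        expl[i] <- explainedFraction(pred[i], meas[i])
        fr <- fractionAccounting(cs, classification, registry, basis)
        frC[i] <- fr[["captured"]]
        frN[i] <- fr[["no_effect_data"]]
        frV[i] <- fr[["volatile_excluded"]]
        semi[i] <- any(st[names(chem$contributions)[
            chem$contributions > 0], sid] == "above_calibration")
        contribs[[i]] <- chem$contributions
    }
    out <- DataFrame(sample_id = bioassays$sample_id,
                     assay = bioassays$assay,
                     endpoint = bioassays$endpoint,
                     predicted = pred, measured = meas,
                     explained_pct = expl,
                     fraction_captured_pct = frC,
                     fraction_no_effect_data_pct = frN,
                     fraction_volatile_pct = frV,
                     semi_quantitative = semi)
    names(contribs) <- paste(out$sample_id, out$assay, out$endpoint,
                             sep = ".")
    out <- as(out, "IcebergResult")
    metadata(out)$contributions <- contribs
    validObject(out)
    out
}
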