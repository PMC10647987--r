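## Seeded generator of complete synthetic chemometer studies with known
## ground truth. The generator emulates the statistical structure the
## analysis assumes -- log-normal tissue burdens with organ-specific
## enrichment, one high-burden individual, per-compound MDL censoring,
## procedural blanks, lipid uptake into the polymer, and bioassay effect
## concentrations back-computed from a configured "explained fraction" --
## so that every pipeline stage can be validated end to end without any
## external data.

#' @importFrom stats rnorm runif setNames
NULL

#' Synthetic-study configuration
#'
#' All tunable condition parameters of [generateStudy()]. The prototype
#' (equivalently [fieldStudyPreset()]) encodes the study design the
#' package targets: 12 animals (harbor porpoises, harbor seals, one
#' ringed seal, one orca), 8 of them with the full organ set (blubber,
#' liver, brain, kidney) and 4 with liver and blubber only (40 extracts),
#' 117 target compounds across 8 substance groups, group-specific
#' log-normal concentration scales, a pyrethroid enrichment in blubber
#' and musk enrichment in liver, an 8-fold contamination multiplier on
#' the orca, lipid uptake of 0.88 +- 0.62% of the PDMS mass, and bioassay
#' measurements for 7 animals whose extract EC/IC values are derived from
#' configured true explained fractions.
#'
#' @slot nAnimals number of animals.
#' @slot fullOrganAnimals how many animals carry all four organs; the
#'   rest have liver and blubber only.
#' @slot highBurdenAnimal index of the high-burden individual (0 = none).
#' @slot contaminationMultiplier burden multiplier of that individual.
#' @slot nCompounds number of target analytes.
#' @slot groupMix named proportions over substance groups (sums to 1).
#' @slot logMu,logSigma named per-group mean and SD of ln c_PDMS (pg/mg);
#'   `logSigma` is the between-sample spread of one compound.
#' @slot compoundSigma ln-scale SD of a per-compound persistent offset
#'   around the group mean, reproducing the strong heterogeneity of
#'   congener patterns (a few dominant congeners, many rare ones).
#' @slot organNoiseSd ln-scale within-animal organ-to-organ noise.
#' @slot organEnrichment group x organ matrix of multiplicative factors.
#' @slot mdlLogMu,mdlLogSigma ln-scale distribution of per-compound MDLs.
#' @slot presentFraction probability that a non-core compound occurs in
#'   the environment at all; a core set (all PCBs, the DDX compounds and
#'   fluorene) is always present. Absent compounds fall far below every
#'   MDL, reproducing the observation that a large minority of target
#'   analytes is never found in any sample.
#' @slot blankFraction fraction of compounds with procedural blanks.
#' @slot blankLevel mean procedural-blank level, pg/mg.
#' @slot calibrationMax concentration above which values are flagged
#'   above-calibration (semi-quantitative), pg/mg.
#' @slot lipidUptakeMean,lipidUptakeSd mean/SD of lipid uptake (g/g PDMS).
#' @slot bioassayAnimals how many animals (always including the
#'   high-burden one when present) have bioassay measurements.
#' @slot trueExplainedFraction named true explained fractions per assay
#'   endpoint (`<assay>.<endpoint>`), each in (0, 1.5].
#' @slot noiseSd ln-scale measurement noise on extract EC/IC values.
#' @slot seed default random seed.
#' @export
setClass("SynthConfig",
    representation(nAnimals = "integer", fullOrganAnimals = "integer",
                   highBurdenAnimal = "integer",
                   contaminationMultiplier = "numeric",
                   nCompounds = "integer", groupMix = "numeric",
                   logMu = "numeric", logSigma = "numeric",
                   compoundSigma = "numeric",
                   organNoiseSd = "numeric", organEnrichment = "matrix",
                   mdlLogMu = "numeric", mdlLogSigma = "numeric",
                   presentFraction = "numeric",
                   blankFraction = "numeric", blankLevel = "numeric",
                   calibrationMax = "numeric",
                   lipidUptakeMean = "numeric", lipidUptakeSd = "numeric",
                   bioassayAnimals = "integer",
                   trueExplainedFraction = "numeric",
                   noiseSd = "numeric", seed = "integer"),
    prototype(
        nAnimals = 12L, fullOrganAnimals = 8L, highBurdenAnimal = 12L,
        contaminationMultiplier = 8,
        nCompounds = 117L,
        groupMix = c(PCB = 13, PAH = 16, OCP = 15, BDE = 8,
                     Pyrethroid = 8, CHC = 6, Musk = 6, Other = 45) / 117,
        logMu = log(c(PCB = 25, PAH = 5, OCP = 15, BDE = 4,
                      Pyrethroid = 3, CHC = 2, Musk = 4, Other = 5)),
        logSigma = c(PCB = 1.2, PAH = 1.2, OCP = 1.2, BDE = 1.2,
                     Pyrethroid = 1.2, CHC = 1.2, Musk = 1.2, Other = 1.2),
        compoundSigma = 1.2,
        organNoiseSd = 0.3,
        organEnrichment = {
            m <- matrix(1, 8, 4, dimnames = list(
                c("PCB", "PAH", "OCP", "BDE", "Pyrethroid", "CHC",
                  "Musk", "Other"),
                c("blubber", "liver", "brain", "kidney")))
            m["Pyrethroid", "blubber"] <- 12
            m["Musk", "liver"] <- 3
            m
        },
        mdlLogMu = log(3), mdlLogSigma = 0.8,
        presentFraction = 0.55,
        blankFraction = 0.2, blankLevel = 0.5,
        calibrationMax = 1000,
        lipidUptakeMean = 0.0088, lipidUptakeSd = 0.0062,
        bioassayAnimals = 7L,
        trueExplainedFraction = c(ahr_calux.activation = 0.2,
                                  arec32.activation = 0.001,
                                  pparg_bla.activation = 0.001,
                                  ahr_calux.cytotoxicity = 0.1),
        noiseSd = 0, seed = 1L))

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (object@nAnimals < 1L) msg <- c(msg, "nAnimals must be >= 1")
    if (object@fullOrganAnimals > object@nAnimals)
        msg <- c(msg, "fullOrganAnimals cannot exceed nAnimals")
    if (object@highBurdenAnimal > object@nAnimals)
        msg <- c(msg, "highBurdenAnimal out of range")
    if (abs(sum(object@groupMix) - 1) > 1e-9)
        msg <- c(msg, "groupMix proportions must sum to 1")
    if (!all(names(object@groupMix) %in% .COMPOUND_GROUPS))
        msg <- c(msg, "groupMix names must be known groups")
    if (any(object@logSigma <= 0))
        msg <- c(msg, "logSigma must be > 0")
    if (object@compoundSigma < 0)
        msg <- c(msg, "compoundSigma must be >= 0")
    f <- object@trueExplainedFraction
    if (any(f <= 0 | f > 1.5))
        msg <- c(msg, "trueExplainedFraction must lie in (0, 1.5]")
    if (object@presentFraction <= 0 || object@presentFraction > 1)
        msg <- c(msg, "presentFraction must lie in (0, 1]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @rdname SynthConfig-class
#' @param ... slots to override, as `slot = value` pairs.
#' @return a validated `SynthConfig`.
#' @export
SynthConfig <- function(...) {
    args <- list(...)
    for (nm in c("nAnimals", "fullOrganAnimals", "highBurdenAnimal",
                 "nCompounds", "bioassayAnimals", "seed"))
        if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
    do.call(new, c(list("SynthConfig"), args))
}

#' The frozen study-like preset
#'
#' @return the default [SynthConfig-class] (see its help page for the
#'   design it encodes).
#' @export
fieldStudyPreset <- function() SynthConfig()

## Stable per-entity substream: a seed derived by hashing the entity
## label, so adding animals or assays never perturbs existing draws.
.entitySeed <- function(seed, entity) {
    h <- 0
    for (ch in utf8ToInt(entity)) h <- (h * 31 + ch) %% 2147483647
    as.integer((h + (seed %% 2147483647) * 48271) %% 2147483647)
}

.withStream <- function(seed, entity, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(list = ".Random.seed",
                                     envir = globalenv())))
    set.seed(.entitySeed(seed, entity))
    force(expr)
}

.NAME_POOL <- list(
    PCB = paste0("PCB", c(18, 28, 52, 101, 105, 118, 135, 138, 149, 153,
                          170, 180, 187)),
    PAH = c("fluorene", "phenanthrene", "anthracene", "fluoranthene",
            "pyrene", "benzo[a]pyrene", "benz[a]anthracene", "chrysene",
            "benzo[b]fluorene", "naphthalene", "acenaphthene",
            "acenaphthylene", "benzo[k]fluoranthene",
            "benzo[ghi]perylene", "indeno[1,2,3-cd]pyrene",
            "dibenz[a,h]anthracene"),
    OCP = c("4,4'-DDE", "4,4'-DDD", "4,4'-DDT", "HCB", "dieldrin",
            "alpha-HCH", "beta-HCH", "gamma-HCH", "delta-HCH",
            "chlordane", "heptachlor", "mirex", "endosulfan-alpha",
            "methoxychlor", "aldrin"),
    BDE = paste0("BDE", c(28, 47, 99, 100, 153, 154, 183, 209)),
    Pyrethroid = c("permethrin", "cypermethrin", "deltamethrin",
                   "etofenprox", "bifenthrin", "fenvalerate",
                   "cyhalothrin", "tefluthrin"),
    CHC = c("hexachlorobutadiene", "pentachlorobenzene",
            "1,2,4-trichlorobenzene", "hexachloroethane",
            "pentachloroanisole", "octachlorostyrene"),
    Musk = c("galaxolide", "tonalide", "musk xylene", "musk ketone",
             "celestolide", "phantolide"),
    Other = character())

.TYPICAL_MASS <- c(PCB = 326, PAH = 202, OCP = 330, BDE = 485,
                   Pyrethroid = 400, CHC = 250, Musk = 258, Other = 300)

## effect-data casting by compound name (applied where present)
.AHR_ACTIVE <- c("PCB105", "PCB118", "PCB138", "PCB180",
                 "benzo[a]pyrene", "benz[a]anthracene", "chrysene",
                 "pyrene", "fluoranthene", "BDE47", "BDE99",
                 "ethylene glycol diphenyl ether")
.AREC32_ACTIVE <- c("anthracene", "benz[a]anthracene", "fluoranthene",
                    "endosulfan-alpha", "bis(4-chlorophenyl)sulfone")
.PPARG_ACTIVE <- c("PCB28", "fluoranthene", "phenanthrene", "BDE47")
.CYTOTOX_ACTIVE <- c(paste0("PCB", c(101, 118, 135, 138, 149, 153, 170,
                                     180)),
                     "fluoranthene", "pyrene", "phenanthrene",
                     "anthracene", "4,4'-DDE", "4,4'-DDD", "4,4'-DDT",
                     "BDE47", "BDE99", "permethrin", "cypermethrin",
                     "etofenprox", "galaxolide", "tonalide")
.TESTED_INACTIVE <- c("PCB18", "PCB52", "PCB187", "fluorene", "HCB",
                      "dieldrin", "chlordane", "heptachlor", "mirex",
                      "BDE100", "BDE153", "musk xylene", "deltamethrin")
.VOLATILE <- c("hexachlorobutadiene", "pentachlorobenzene",
               "1,2,4-trichlorobenzene", "hexachloroethane",
               "pentachloroanisole", "octachlorostyrene", "naphthalene",
               "acenaphthene", "acenaphthylene")

.groupCounts <- function(config) {
    n <- config@nCompounds
    p <- config@groupMix
    cnt <- floor(p * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
        extra <- order(p * n - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[extra] <- cnt[extra] + 1L
    }
    cnt
}

.genRegistry <- function(config, seed) {
    cnt <- .groupCounts(config)
    groups <- rep(names(cnt), cnt)
    nm <- unlist(lapply(names(cnt), function(g) {
        pool <- .NAME_POOL[[g]]
        k <- cnt[[g]]
        base <- pool[seq_len(min(k, length(pool)))]
        if (k > length(pool))
            base <- c(base, sprintf("%s_synth_%02d", tolower(g),
                                    seq_len(k - length(pool))))
        base
    }), use.names = FALSE)
    .withStream(seed, "registry", {
        mm <- .TYPICAL_MASS[groups] * exp(rnorm(length(nm), 0, 0.15))
        mdl <- exp(rnorm(length(nm), config@mdlLogMu, config@mdlLogSigma))
        ## experimental K_lipid/PDMS for PCBs, some PAHs/OCPs/CHCs
        kexp <- rep(NA_real_, length(nm))
        expIdx <- c(which(groups == "PCB"),
                    which(groups == "PAH")[seq_len(min(8, sum(groups == "PAH")))],
                    which(groups == "OCP")[seq_len(min(8, sum(groups == "OCP")))],
                    which(groups == "CHC")[seq_len(min(2, sum(groups == "CHC")))])
        kexp[expIdx] <- exp(rnorm(length(expIdx), log(21), 0.35))
        logKow <- runif(length(nm), 4, 8.5)
        volatile <- nm %in% .VOLATILE
        logKma <- ifelse(volatile, runif(length(nm), 2, 3.9),
                         runif(length(nm), 4.5, 9))
        tested <- (nm %in% c(.AHR_ACTIVE, .AREC32_ACTIVE, .PPARG_ACTIVE,
                             .CYTOTOX_ACTIVE, .TESTED_INACTIVE)) & !volatile
        ecDraw <- function(active, lo, hi) {
            v <- rep(NA_real_, length(nm))
            sel <- nm %in% active & tested
            v[sel] <- 10^runif(sum(sel), lo, hi)
            v
        }
        ecAhr <- ecDraw(.AHR_ACTIVE, -9, -6)
        ecAhr[nm == "benzo[a]pyrene"] <- 3e-10
        ecAre <- ecDraw(.AREC32_ACTIVE, -6, -4.5)
        ecAre[nm == "benzo[a]pyrene" & tested[match("benzo[a]pyrene", nm)]] <- 5e-6
        ecPparg <- ecDraw(.PPARG_ACTIVE, -6, -4.5)
        icAhr <- ecDraw(.CYTOTOX_ACTIVE, -5.5, -4)
        df <- DataFrame(
            compound_id = gsub("[^A-Za-z0-9]+", "_", nm),
            name = nm, group = groups,
            molar_mass_g_mol = mm, mdl_pg_mg = mdl,
            k_lipid_pdms = kexp, log_kow = logKow,
            log_k_medium_air = logKma, effect_tested = tested,
            ec_ahr_calux_mol_l = ecAhr, ec_arec32_mol_l = ecAre,
            ec_pparg_bla_mol_l = ecPparg, ic_ahr_calux_mol_l = icAhr)
        out <- as(df, "CompoundRegistry")
        rownames(out) <- out$compound_id
        validObject(out)
        out
    })
}

.speciesPattern <- function(n) {
    base <- c(rep("harbor_porpoise", 7), rep("harbor_seal", 3),
              "ringed_seal", "orca")
    rep(base, length.out = n)
}

.LIPID_RANGES <- list(blubber = c(0.37, 0.95), liver = c(0.019, 0.23),
                      brain = c(0.068, 0.12), kidney = c(0.02, 0.039))

.CORE_PRESENT <- c("4,4'-DDE", "4,4'-DDD", "4,4'-DDT", "fluorene")

.genPresence <- function(config, seed, registry) {
    .withStream(seed, "presence", {
        core <- registry$group == "PCB" | registry$name %in% .CORE_PRESENT
        core | runif(nrow(registry)) < config@presentFraction
    })
}

.genOffsets <- function(config, seed, registry) {
    .withStream(seed, "compound-offsets",
                exp(rnorm(nrow(registry), 0, config@compoundSigma)))
}

.genAnimal <- function(config, seed, i, registry, present, offset) {
    organs <- if (i <= config@fullOrganAnimals)
        c("blubber", "liver", "brain", "kidney") else c("blubber", "liver")
    species <- .speciesPattern(config@nAnimals)[i]
    animalId <- sprintf("A%02d", i)
    mult <- if (i == config@highBurdenAnimal)
        config@contaminationMultiplier else 1
    .withStream(seed, paste0("animal:", i), {
        lf <- vapply(organs, function(o)
            runif(1, .LIPID_RANGES[[o]][1], .LIPID_RANGES[[o]][2]),
            numeric(1))
        pdms <- runif(length(organs), 60, 250)
        uptake <- pmax(rnorm(length(organs), config@lipidUptakeMean,
                             config@lipidUptakeSd), 5e-4)
        smp <- DataFrame(
            sample_id = paste0(animalId, "_", organs),
            animal_id = animalId, species = species, organ = organs,
            lipid_fraction = lf, pdms_mass_mg = pdms,
            lipid_uptake_fraction = uptake)
        grp <- registry$group
        base <- exp(rnorm(nrow(registry), config@logMu[grp],
                          config@logSigma[grp])) * offset * mult *
            ifelse(present, 1, 1e-10)   # absent compounds sit far below MDL
        conc <- vapply(organs, function(o) {
            enr <- config@organEnrichment[grp, o]
            base * enr * exp(rnorm(nrow(registry), 0, config@organNoiseSd))
        }, numeric(nrow(registry)))
        conc <- matrix(conc, nrow(registry), length(organs),
                       dimnames = list(registry$compound_id,
                                       smp$sample_id))
        list(samples = smp, conc = conc)
    })
}

#' Generate a complete synthetic chemometer study
#'
#' Draws a full study from a [SynthConfig-class]: compound registry,
#' samples, latent true concentrations, a raw (naive) concentration
#' table carrying blank contamination and lipid-uptake dilution,
#' procedural blanks, effect datasets, and a bioassay panel whose
#' extract EC/IC values are back-computed so that the true explained
#' fraction per assay endpoint equals the configured value (before
#' optional ln-scale measurement noise). Output is deterministic for a
#' fixed seed, with one pseudorandom substream per entity so that adding
#' animals never perturbs existing draws. The ground truth is returned
#' as a separate element the pipeline never reads.
#'
#' @param config a [SynthConfig-class].
#' @param seed integer seed (defaults to the config's).
#' @return list with elements `registry`, `samples`, `concRaw` (the raw
#'   [ConcentrationTable-class] to feed to [quantifyPipeline()]),
#'   `blanks`, `effects` (list of [EffectDataset-class]), `bioassays`
#'   (a [BioassayPanel], possibly empty) and `groundTruth` (list with
#'   the latent concentration matrix, the processed true table, true
#'   BEQ/TU sums and the configured explained fractions).
#' @examples
#' study <- generateStudy(SynthConfig(nAnimals = 3, fullOrganAnimals = 3,
#'                                    highBurdenAnimal = 0,
#'                                    nCompounds = 40, bioassayAnimals = 2))
#' conc <- quantifyPipeline(study$concRaw, study$blanks)
#' @export
generateStudy <- function(config = fieldStudyPreset(), seed = config@seed) {
    validObject(config)
    registry <- .genRegistry(config, seed)
    present <- .genPresence(config, seed, registry)
    offset <- .genOffsets(config, seed, registry)
    per <- lapply(seq_len(config@nAnimals), function(i)
        .genAnimal(config, seed, i, registry, present, offset))
    samples <- do.call(rbind, lapply(per, `[[`, "samples"))
    samples <- as(samples, "SampleTable")
    rownames(samples) <- samples$sample_id
    latent <- do.call(cbind, lapply(per, `[[`, "conc"))

    ## procedural blanks for a fixed fraction of compounds
    blanks <- .withStream(seed, "blanks", {
        nb <- ceiling(config@blankFraction * nrow(registry))
        ids <- sort(sample(registry$compound_id, nb))
        setNames(lapply(ids, function(id)
            abs(rnorm(3, config@blankLevel, config@blankLevel / 4))), ids)
    })
    meanBlank <- setNames(rep(0, nrow(registry)), registry$compound_id)
    meanBlank[names(blanks)] <- vapply(blanks, mean, numeric(1))

    ## invert the quantification pipeline: the raw (naive, per-PDMS-mass)
    ## value carries the lipid-uptake dilution and the blank on top of
    ## the latent concentration
    k <- partitionK(registry, PartitionPolicy())
    u <- samples$lipid_uptake_fraction
    raw <- latent * (1 + outer(k, u)) + meanBlank
    status <- matrix(ifelse(latent > config@calibrationMax,
                            "above_calibration", "detected"),
                     nrow(raw), ncol(raw), dimnames = dimnames(raw))
    concRaw <- ConcentrationTable(raw, status, registry, samples)

    ## processed truth and effect datasets
    concTrue <- quantifyPipeline(concRaw, blanks)
    effects <- .studyEffects(registry)

    ## bioassay panel back-computed from the configured explained fraction
    bioAnimals <- unique(samples$animal_id)[
        seq_len(min(config@bioassayAnimals, config@nAnimals))]
    if (config@highBurdenAnimal >= 1L) {
        hb <- sprintf("A%02d", config@highBurdenAnimal)
        if (!hb %in% bioAnimals && length(bioAnimals))
            bioAnimals[length(bioAnimals)] <- hb
    }
    bioSamples <- samples$sample_id[samples$animal_id %in% bioAnimals]
    cc <- concMatrix(concTrue)
    rows <- list()
    truth <- list()
    for (key in names(config@trueExplainedFraction)) {
        parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
        eff <- effects[[key]]
        if (is.null(eff)) next
        f <- config@trueExplainedFraction[[key]]
        for (sid in bioSamples) {
            cs <- setNames(cc[, sid], rownames(cc))
            chem <- if (parts[2L] == "activation")
                beqChem(cs, eff, registry)$total
            else tuChem(cs, eff, registry)$total
            if (chem <= 0) next
            ecx <- if (parts[2L] == "activation")
                eff@ecReference * f / chem else f / chem
            noise <- .withStream(seed, paste0("bio:", key, ":", sid),
                                 exp(rnorm(1, 0, config@noiseSd)))
            rows[[length(rows) + 1L]] <- DataFrame(
                sample_id = sid, assay = parts[1L], endpoint = parts[2L],
                ec_extract_kg_l = ecx * noise,
                reference_compound = eff@referenceCompound,
                ec_reference_mol_l = eff@ecReference)
            truth[[length(truth) + 1L]] <- DataFrame(
                sample_id = sid, assay = parts[1L], endpoint = parts[2L],
                chem_true = chem, f_true = f)
        }
    }
    bioassays <- if (length(rows)) as(do.call(rbind, rows), "BioassayPanel")
        else new("BioassayPanel", DataFrame(
            sample_id = character(), assay = character(),
            endpoint = character(), ec_extract_kg_l = numeric(),
            reference_compound = character(),
            ec_reference_mol_l = numeric()))

    list(registry = registry, samples = samples, concRaw = concRaw,
         blanks = blanks, effects = effects, bioassays = bioassays,
         groundTruth = list(
             present = setNames(present, registry$compound_id),
             compoundOffset = setNames(offset, registry$compound_id),
             latent = latent,
             concTrue = concTrue,
             chemTrue = if (length(truth)) do.call(rbind, truth)
                        else DataFrame(),
             trueExplainedFraction = config@trueExplainedFraction))
}

## assemble the study's four effect datasets from the registry
.studyEffects <- function(registry) {
    out <- list()
    refOf <- function(col, preferred) {
        ec <- registry[[col]]
        if (preferred %in% registry$name &&
            !is.na(ec[match(preferred, registry$name)]))
            return(list(id = registry$compound_id[match(preferred,
                                                        registry$name)],
                        ec = ec[match(preferred, registry$name)]))
        ok <- which(!is.na(ec))
        if (!length(ok)) return(NULL)
        list(id = registry$compound_id[ok[1L]], ec = ec[ok[1L]])
    }
    spec <- list(
        c("ahr_calux", "activation", "ec_ahr_calux_mol_l",
          "benzo[a]pyrene"),
        c("arec32", "activation", "ec_arec32_mol_l", "benzo[a]pyrene"),
        c("pparg_bla", "activation", "ec_pparg_bla_mol_l", "rosiglitazone"),
        c("ahr_calux", "cytotoxicity", "ic_ahr_calux_mol_l",
          "benzo[a]pyrene"))
    for (s in spec) {
        if (!s[3L] %in% colnames(registry)) next
        ref <- refOf(s[3L], s[4L])
        if (is.null(ref)) next
        out[[paste(s[1L], s[2L], sep = ".")]] <-
            effectDatasetFromRegistry(registry, s[1L], s[2L],
                                      referenceCompound = ref$id,
                                      ecReference = ref$ec)
    }
    out
}

#' Write / read a synthetic study as CSV files
#'
#' `writeStudy()` emits the study as the package's CSV schemas
#' (`compounds.csv`, `samples.csv`, `concentrations_raw.csv`,
#' `blanks.csv`, `bioassays.csv`) plus `ground_truth.csv`, which holds
#' the synthetic latent values and is never read back by the pipeline.
#' `readStudy()` reads the pipeline-facing files back.
#'
#' @param study a list as returned by [generateStudy()].
#' @param dir output directory (created if needed).
#' @return `writeStudy()` the directory, invisibly; `readStudy()` a list
#'   with `registry`, `samples`, `concRaw`, `blanks`, `bioassays`.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCompoundRegistry(study$registry, file.path(dir, "compounds.csv"))
    writeSampleTable(study$samples, file.path(dir, "samples.csv"))
    writeConcentrationTable(study$concRaw,
                            file.path(dir, "concentrations_raw.csv"))
    bl <- data.frame(
        compound_id = rep(names(study$blanks),
                          vapply(study$blanks, length, integer(1))),
        value_pg_mg = unlist(study$blanks, use.names = FALSE))
    write.csv(bl, file.path(dir, "blanks.csv"), row.names = FALSE)
    writeBioassayPanel(study$bioassays, file.path(dir, "bioassays.csv"))
    gt <- as.data.frame(study$groundTruth$chemTrue)
    write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    invisible(dir)
}

#' @rdname writeStudy
#' @export
readStudy <- function(dir) {
    registry <- readCompoundRegistry(file.path(dir, "compounds.csv"))
    samples <- readSampleTable(file.path(dir, "samples.csv"))
    concRaw <- readConcentrationTable(file.path(dir,
                                                "concentrations_raw.csv"),
                                      registry, samples)
    bl <- .readCsv(file.path(dir, "blanks.csv"))
    blanks <- split(bl$value_pg_mg, bl$compound_id)
    bioassays <- readBioassayPanel(file.path(dir, "bioassays.csv"),
                                   samples)
    list(registry = registry, samples = samples, concRaw = concRaw,
         blanks = blanks, bioassays = bioassays)
}
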