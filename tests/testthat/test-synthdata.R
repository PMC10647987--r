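test_that("generation is deterministic and stable under added animals", {
    cfg <- smallConfig()
    s1 <- generateStudy(cfg, seed = 5)
    s2 <- generateStudy(cfg, seed = 5)
    expect_identical(concMatrix(s1$concRaw), concMatrix(s2$concRaw))
    expect_identical(s1$bioassays$ec_extract_kg_l,
                     s2$bioassays$ec_extract_kg_l)
    expect_false(identical(concMatrix(s1$concRaw),
                           concMatrix(generateStudy(cfg, seed = 6)$concRaw)))
    ## per-entity streams: adding an animal leaves earlier draws intact
    bigger <- generateStudy(SynthConfig(nAnimals = 5, fullOrganAnimals = 5,
                                        highBurdenAnimal = 0,
                                        nCompounds = 40,
                                        bioassayAnimals = 3), seed = 5)
    shared <- colnames(concMatrix(s1$concRaw))
    expect_identical(concMatrix(bigger$concRaw)[, shared],
                     concMatrix(s1$concRaw)[, shared])
})

test_that("the quantification pipeline inverts the generative model", {
    study <- generateStudy(smallConfig(), seed = 3)
    conc <- quantifyPipeline(study$concRaw, study$blanks)
    truth <- concMatrix(study$groundTruth$concTrue)
    expect_equal(concMatrix(conc), truth)
    ## censoring happened against the registry MDLs
    expect_true(validateStudy(conc))
    ## the latent values that survive equal the processed values
    latent <- study$groundTruth$latent
    det <- isDetected(conc)
    expect_equal(concMatrix(conc)[det], latent[det], tolerance = 1e-12)
})

test_that("explained fractions recover the configured ground truth without noise", {
    study <- generateStudy(smallConfig(), seed = 9)
    conc <- quantifyPipeline(study$concRaw, study$blanks)
    res <- runIceberg(conc, study$effects, study$bioassays)
    f <- study$groundTruth$trueExplainedFraction
    for (i in seq_len(nrow(res))) {
        key <- paste(res$assay[i], res$endpoint[i], sep = ".")
        expect_equal(res$explained_pct[i], 100 * f[[key]],
                     tolerance = 1e-9)
    }
    expect_gt(nrow(res), 0L)
})

test_that("a unit explained fraction with zero noise closes the loop at 100%", {
    cfg <- smallConfig(trueExplainedFraction = c(
        ahr_calux.activation = 1.0, ahr_calux.cytotoxicity = 1.0))
    study <- generateStudy(cfg, seed = 2)
    conc <- quantifyPipeline(study$concRaw, study$blanks)
    res <- runIceberg(conc, study$effects, study$bioassays)
    expect_equal(res$explained_pct, rep(100, nrow(res)),
                 tolerance = 1e-9)
})

test_that("nondetect rates match the analytic log-normal tail probability", {
    ## single-group config so the tail probability is in closed form
    cfg <- SynthConfig(nAnimals = 30, fullOrganAnimals = 0,
                       highBurdenAnimal = 0, nCompounds = 20,
                       groupMix = c(PCB = 1),
                       logMu = c(PCB = log(10)), logSigma = c(PCB = 1.2),
                       compoundSigma = 0,
                       organNoiseSd = 1e-9, mdlLogMu = log(8),
                       mdlLogSigma = 1e-9, blankFraction = 0,
                       bioassayAnimals = 0)
    study <- generateStudy(cfg, seed = 21)
    conc <- quantifyPipeline(study$concRaw, study$blanks)
    ## organ values duplicate the animal draw, so one draw per animal
    det <- isDetected(conc)[, sampleData(conc)$organ == "liver"]
    pND <- pnorm((log(8) - log(10)) / 1.2)
    n <- length(det)
    phat <- 1 - mean(det)
    expect_lt(abs(phat - pND), 3 * sqrt(pND * (1 - pND) / n))
})

test_that("configured organ enrichment is recovered by the ratio test", {
    cfg <- SynthConfig(nAnimals = 40, fullOrganAnimals = 0,
                       highBurdenAnimal = 0, nCompounds = 10,
                       groupMix = c(Pyrethroid = 1),
                       logMu = c(Pyrethroid = log(50)),
                       logSigma = c(Pyrethroid = 0.8),
                       organNoiseSd = 0.3,
                       organEnrichment = {
                           m <- matrix(1, 8, 4, dimnames = list(
                               c("PCB", "PAH", "OCP", "BDE", "Pyrethroid",
                                 "CHC", "Musk", "Other"),
                               c("blubber", "liver", "brain", "kidney")))
                           m["Pyrethroid", "blubber"] <- 10
                           m
                       },
                       mdlLogMu = log(0.01), blankFraction = 0,
                       presentFraction = 1, bioassayAnimals = 0)
    study <- generateStudy(cfg, seed = 13)
    conc <- quantifyPipeline(study$concRaw, study$blanks)
    cid <- rownames(conc)[1]
    res <- organRatioTest(conc, cid, numeratorOrgan = "blubber",
                          denominatorOrgan = "liver")
    ## GM ratio approx 10 within its own 95% CI
    expect_gt(res@ciHigh, 10 * 0.99)
    expect_lt(res@ciLow, 10 * 1.01)
    expect_equal(res@gmRatio, 10, tolerance = 0.3)
})

test_that("the study-like preset has the documented structure", {
    study <- generateStudy(fieldStudyPreset())
    expect_equal(nrow(study$registry), 117L)
    expect_equal(nrow(study$samples), 40L)
    expect_equal(length(unique(study$samples$animal_id)), 12L)
    conc <- quantifyPipeline(study$concRaw, study$blanks)
    df <- detectionFrequency(conc)
    ## at least one compound detected in >= 90% of extracts
    expect_gte(max(df$pct_detected), 90)
    ## detected-compound count strictly between 0 and n
    nDet <- sum(df$n_detected > 0)
    expect_gt(nDet, 0L)
    expect_lt(nDet, 117L)
    ## removing the high-burden animal lowers the maximum PCB burden
    pcb <- compoundData(conc)$compound_id[compoundData(conc)$group == "PCB"]
    studyNo <- generateStudy(SynthConfig(highBurdenAnimal = 0L))
    concNo <- quantifyPipeline(studyNo$concRaw, studyNo$blanks)
    expect_lt(max(sumBurden(concNo, pcb)), max(sumBurden(conc, pcb)))
    ## the orca carries the maximum burden
    smp <- sampleData(conc)
    expect_equal(unique(smp$species[smp$sample_id ==
        names(which.max(sumBurden(conc, pcb)))]), "orca")
})

test_that("studies round-trip through the CSV schemas", {
    dir <- withr::local_tempdir()
    study <- generateStudy(smallConfig(), seed = 8)
    writeStudy(study, dir)
    back <- readStudy(dir)
    expect_equal(concMatrix(back$concRaw), concMatrix(study$concRaw))
    expect_equal(back$registry$mdl_pg_mg, study$registry$mdl_pg_mg)
    expect_equal(back$bioassays$ec_extract_kg_l,
                 study$bioassays$ec_extract_kg_l)
    ## blanks survive with their replicate structure
    expect_equal(sort(names(back$blanks)), sort(names(study$blanks)))
    p1 <- quantifyPipeline(study$concRaw, study$blanks)
    p2 <- quantifyPipeline(back$concRaw, back$blanks)
    expect_equal(concMatrix(p1), concMatrix(p2))
})
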