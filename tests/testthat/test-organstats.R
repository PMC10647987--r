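test_that("detection frequencies count detected entries per compound", {
    ct <- toyTable()
    df <- detectionFrequency(ct)
    expect_equal(df$n_detected[df$compound_id == "pcb153"], 4L)
    expect_equal(df$pct_detected[df$compound_id == "pcb153"], 100)
    expect_equal(df$n_detected[df$compound_id == "flu"], 3L)
    ## never-detected compounds still reported, at 0%
    cc <- concMatrix(ct)
    cc["volat", ] <- NA
    ct0 <- toyTable(cc)
    df0 <- detectionFrequency(ct0)
    expect_equal(df0$pct_detected[df0$compound_id == "volat"], 0)
})

test_that("geometric summaries match the log-domain and product oracles", {
    gs <- geoSummary(c(10, 10, 10))
    expect_equal(gs$gm, 10)
    expect_equal(gs$gsd, 1)
    expect_equal(geoSummary(c(1, 100))$gm, 10)
    gs2 <- geoSummary(c(2, 4, 8))
    expect_equal(gs2$gm, 4)
    expect_equal(gs2$gsd, exp(sd(log(c(2, 4, 8)))))
    ## naive product^(1/n) oracle, n <= 12
    for (n in c(2, 5, 12)) {
        set.seed(n)
        x <- exp(rnorm(n, 2, 1))
        expect_equal(geoSummary(x)$gm, prod(x)^(1 / n), tolerance = 1e-10)
    }
    expect_error(geoSummary(c(1, 0)), "positive")
})

test_that("ratio paired t-test matches a closed-form oracle", {
    set.seed(42)
    num <- exp(rnorm(10, 1, 0.5))
    den <- exp(rnorm(10, 0.5, 0.5))
    res <- ratioPairedTTest(num, den)
    d <- log(num) - log(den)
    se <- sd(d) / sqrt(10)
    expect_equal(res@gmRatio, exp(mean(d)))
    expect_equal(res@ciLow, exp(mean(d) - qt(0.975, 9) * se))
    expect_equal(res@ciHigh, exp(mean(d) + qt(0.975, 9) * se))
    tstat <- mean(d) / se
    expect_equal(res@pValue, 2 * pt(-abs(tstat), 9))
})

test_that("ratio paired t-test is reciprocally symmetric and handles degeneracy", {
    set.seed(1)
    num <- exp(rnorm(8, 1, 0.4))
    den <- exp(rnorm(8, 0, 0.4))
    fwd <- ratioPairedTTest(num, den)
    rev <- ratioPairedTTest(den, num)
    expect_equal(fwd@gmRatio, 1 / rev@gmRatio)
    expect_equal(fwd@ciLow, 1 / rev@ciHigh)
    expect_equal(fwd@ciHigh, 1 / rev@ciLow)
    expect_equal(fwd@pValue, rev@pValue)
    ## constant ratio: GM exact, CI degenerate
    cst <- ratioPairedTTest(c(2, 4, 8), c(1, 2, 4))
    expect_equal(cst@gmRatio, 2)
    expect_true(cst@degenerate)
    expect_equal(c(cst@ciLow, cst@ciHigh), c(2, 2))
    ## all pairs equal -> GM 1, flagged
    eq <- ratioPairedTTest(c(3, 3), c(3, 3))
    expect_equal(eq@gmRatio, 1)
    expect_true(eq@degenerate)
    ## single pair: point estimate only
    single <- ratioPairedTTest(c(4, NA), c(2, 5))
    expect_equal(single@gmRatio, 2)
    expect_equal(single@nPairs, 1L)
    expect_true(is.na(single@pValue))
    ## nondetect pairs are dropped, not imputed
    res <- ratioPairedTTest(c(2, 4, NA), c(1, 2, 9))
    expect_equal(res@nPairs, 2L)
})

test_that("organ ratio test pairs organs within animals", {
    ct <- toyTable()
    res <- organRatioTest(ct, "pcb153")
    ## pairs: (100, 80) and (50, 40) -> constant ratio 1.25
    expect_equal(res@gmRatio, 1.25)
    expect_equal(res@nPairs, 2L)
    ## summed burden over the PCB set
    res2 <- organRatioTest(ct, c("pcb153", "pcb138"))
    expect_equal(res2@gmRatio, exp(mean(log(c(160 / 130, 80 / 65)))))
    expect_error(organRatioTest(ct, "nosuch"), "nosuch")
})

test_that("group profiles sum to 100 on mass and molar bases", {
    ct <- toyTable()
    for (basis in c("mass", "molar")) {
        prof <- groupProfile(ct, basis)
        expect_equal(unname(rowSums(prof)), rep(100, 4),
                     tolerance = 1e-9)
    }
    prof <- groupProfile(ct)
    expect_equal(prof["a1_liver", "PCB"], 100 * 160 / 215)
    expect_equal(unname(prof["a1_liver", c("BDE", "Musk")]), c(0, 0))
})

test_that("threshold assessment uses strict exceedance and is monotone", {
    ct <- censorTable(toyTable())
    rules <- defaultThresholdRules(compoundData(ct))
    expect_equal(rules$value_mg_kg, c(9, 11, 41, 1))
    res <- assessThresholds(ct, rules)
    expect_equal(dim(res$exceeded), c(4L, 4L))
    ## hand-checked lipid-based PCB sum of a1_liver:
    ## (100 * 25 + 60 * 21) * 1e-3 = 3.76 mg/kg -> below threshold I
    expect_equal(res$burden["a1_liver", "PCB_I_onset"], 3.76)
    expect_false(res$exceeded["a1_liver", "PCB_I_onset"])

    ## boundary: a burden exactly at the threshold does not transgress
    cc <- concMatrix(ct)
    cc["pcb153", "a1_liver"] <- 9.0 / (25 * 1e-3)
    cc["pcb138", "a1_liver"] <- NA
    st <- statusMatrix(ct); st["pcb138", "a1_liver"] <- "nondetect"
    at <- toyTable(cc, st)
    resAt <- assessThresholds(at, rules)
    expect_equal(resAt$burden["a1_liver", "PCB_I_onset"], 9.0)
    expect_false(resAt$exceeded["a1_liver", "PCB_I_onset"])

    ## monotone: scaling all concentrations up never clears an exceedance
    up <- toyTable(concMatrix(ct) * 50, statusMatrix(ct))
    resUp <- assessThresholds(up, rules)
    expect_true(all(resUp$exceeded >= res$exceeded))
    ## per-animal summary counts animals with >= 1 exceeding organ
    expect_equal(unname(resUp$n_animals_exceeding["PCB_I_onset"]), 2L)
})

test_that("wet-weight DDX burden uses the lipid fraction", {
    ct <- censorTable(toyTable())
    rules <- defaultThresholdRules(compoundData(ct))
    ddx <- sumBurden(ct, "dde", basis = "wet")
    lip <- sumBurden(ct, "dde", basis = "lipid")
    expect_equal(ddx, lip * sampleData(ct)$lipid_fraction)
    ## a1_blubber: 90 pg/mg * K 30 * 1e-3 * lf 0.6 = 1.62 mg/kg ww > 1
    expect_equal(unname(ddx["a1_blubber"]), 90 * 30 * 1e-3 * 0.6)
    res <- assessThresholds(ct, rules)
    expect_true(res$exceeded["a1_blubber", "DDX_toxicity"])
})
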