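test_that("MDL matches the published t-table oracle for n = 3..10", {
    ## oracle: SD by definition, t quantile from an independent printed
    ## table (two-tailed 99%)
    for (n in 3:10) {
        set.seed(n)
        reps <- abs(rnorm(n, mean = 10))
        sdDef <- sqrt(sum((reps - mean(reps))^2) / (n - 1))
        expected <- T_TABLE_995[[as.character(n - 1)]] * sdDef
        expect_equal(computeMDL(reps), expected, tolerance = 5e-4)
    }
    ## worked reference cases
    expect_equal(computeMDL(c(9, 10, 11, 9.5, 10.5, 10, 9.8, 10.2)) /
                     sd(c(9, 10, 11, 9.5, 10.5, 10, 9.8, 10.2)),
                 3.499, tolerance = 5e-4)
    set.seed(7)
    r7 <- abs(rnorm(7, 10))
    expect_equal(computeMDL(r7 / sd(r7) * 2), 7.415, tolerance = 1e-3)
    ## degenerate and error cases
    expect_equal(computeMDL(rep(5, 4)), 0)
    expect_error(computeMDL(5), "insufficient")
    ## EPA one-tailed variant uses the smaller quantile
    expect_lt(computeMDL(c(1, 2, 3), method = "epa_one_tailed"),
              computeMDL(c(1, 2, 3)))
})

test_that("blank subtraction reduces, censors at zero, and is monotone", {
    ct <- toyTable()
    out <- subtractBlanks(ct, list(pcb153 = c(8, 12)))   # mean 10
    expect_equal(concMatrix(out)["pcb153", "a1_liver"], 90)
    ## untouched compound unchanged
    expect_equal(concMatrix(out)["dde", ], concMatrix(ct)["dde", ])
    ## value driven to or below zero becomes nondetect
    out2 <- subtractBlanks(ct, list(volat = c(10)))
    expect_true(all(statusMatrix(out2)["volat", ] == "nondetect"))
    ## increasing a blank never increases any concentration
    hi <- subtractBlanks(ct, list(pcb153 = 20))
    lo <- subtractBlanks(ct, list(pcb153 = 5))
    expect_true(all(concMatrix(hi)["pcb153", ] <=
                        concMatrix(lo)["pcb153", ]))
    ## unknown compound key is an error
    expect_error(subtractBlanks(ct, list(nosuch = 1)), "nosuch")
})

test_that("lipid-uptake correction follows the two-phase mass balance", {
    ## zero uptake: naive mass / PDMS mass
    expect_equal(correctLipidUptake(1000, 100, 0, 23), 10)
    ## mass-balance oracle: c * (m_pdms + K m_lip) = total mass
    expect_equal(correctLipidUptake(1000, 100, 1, 23), 1000 / 123)
    cOracle <- function(mass, mp, ml, k) {
        f <- function(c) c * (mp + k * ml) - mass
        uniroot(f, c(0, mass))$root
    }
    expect_equal(correctLipidUptake(500, 80, 0.7, 18),
                 cOracle(500, 80, 0.7, 18), tolerance = 1e-6)
    expect_error(correctLipidUptake(10, 0, 1, 23), "pdms")

    ## table form agrees with the scalar form
    ct <- toyTable()
    out <- applyLipidUptakeCorrection(ct)
    k <- partitionK(compoundData(ct))
    u <- sampleData(ct)$lipid_uptake_fraction
    mp <- sampleData(ct)$pdms_mass_mg
    mass <- concMatrix(ct)["pcb153", "a1_liver"] * mp[1]
    expect_equal(concMatrix(out)["pcb153", "a1_liver"],
                 correctLipidUptake(mass, mp[1], u[1] * mp[1],
                                    k[["pcb153"]]))
})

test_that("censoring respects the MDL boundary and is monotone and idempotent", {
    reg <- toyRegistry()
    smp <- toySamples()
    conc <- matrix(c(5, 10, 9.999, 10.5), 1, 4,
                   dimnames = list("x", smp$sample_id))
    reg1 <- reg[1, ]; reg1$compound_id <- "x"; reg1$mdl_pg_mg <- 10
    rownames(reg1) <- "x"
    ct <- ConcentrationTable(conc, registry = reg1, samples = smp)
    out <- censorTable(ct)
    ## strictly below MDL censored; exactly at MDL kept
    expect_equal(unname(statusMatrix(out)[1, ]),
                 c("nondetect", "detected", "nondetect", "detected"))
    ## MDL 0 keeps every positive value
    expect_true(all(isDetected(censorTable(ct, mdl = c(x = 0)))))
    ## idempotent: re-censoring is a no-op
    expect_identical(concMatrix(censorTable(out)), concMatrix(out))
    ## monotone: raising the MDL never increases the detection count
    counts <- vapply(c(0, 5, 10, 11, 100), function(m)
        sum(isDetected(censorTable(ct, mdl = c(x = m)))), numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("pipeline order is fixed and its end state idempotent", {
    study <- generateStudy(smallConfig())
    p1 <- quantifyPipeline(study$concRaw, study$blanks)
    expect_equal(pipelineStages(p1),
                 c("blank_subtracted", "lipid_corrected", "censored"))
    expect_identical(concMatrix(censorTable(p1)), concMatrix(p1))
    expect_true(validateStudy(p1))
})

test_that("synthetic lipid uptake reproduces the targeted sampling conditions", {
    ## the preset emulates in-tissue sampling with ~0.88 +- 0.62% lipid
    ## uptake over the 40-sheet panel
    study <- generateStudy(fieldStudyPreset(), seed = 11)
    u <- 100 * study$samples$lipid_uptake_fraction
    expect_equal(length(u), 40L)
    expect_gt(mean(u), 0.88 - 3 * 0.62 / sqrt(40))
    expect_lt(mean(u), 0.88 + 3 * 0.62 / sqrt(40))
})
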