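test_that("measured BEQ and TU follow their defining ratios", {
    expect_equal(beqBio(1e-9, 1e-3), 1e-6)
    expect_equal(beqBio(1e-9, 0.5e-3), 2e-6)   # halving EC doubles BEQ
    expect_equal(tuBio(1e-4), 1e4)
    expect_error(beqBio(1e-9, 0), "> 0")
    eff <- toyEffects("cytotoxicity")
    expect_error(beqChem(c(pcb153 = 1), eff, toyRegistry()), "activation")
    expect_error(tuChem(c(pcb153 = 1), toyEffects("activation"),
                        toyRegistry()), "cytotoxicity")
})

test_that("BEQ_chem matches a brute-force mole-sum oracle to 10 digits", {
    reg <- toyRegistry()
    eff <- toyEffects("activation")
    cs <- c(pcb153 = 157, pcb138 = 90.2, flu = 12, dde = 40, volat = 2)
    got <- beqChem(cs, eff, reg)
    ## oracle: explicit per-compound mole amounts, REP = ecRef / ec_i
    oracle <- 0
    for (id in names(cs)) {
        ec <- reg[[sprintf("ec_%s_mol_l", "ahr_calux")]][
            match(id, reg$compound_id)]
        if (!reg$effect_tested[match(id, reg$compound_id)] || is.na(ec))
            next
        molPerKg <- cs[[id]] * 1e-12 * 1e6 /
            reg$molar_mass_g_mol[match(id, reg$compound_id)]
        oracle <- oracle + (2e-8 / ec) * molPerKg
    }
    expect_equal(got$total, oracle, tolerance = 1e-10)
    expect_equal(sum(got$contributions), got$total)
    ## inactive-but-tested compound (flu) contributes exactly zero
    expect_equal(got$contributions[["flu"]], 0)
    ## compounds without effect data are not in the map
    expect_false("dde" %in% names(got$contributions))

    ## TU_chem oracle likewise
    gotTu <- tuChem(cs, toyEffects("cytotoxicity"), reg)
    oracleTu <- cs[["pcb153"]] * 1e-6 / 360.88 / 1e-5 +
        cs[["flu"]] * 1e-6 / 166.22 / 3e-5
    expect_equal(gotTu$total, oracleTu, tolerance = 1e-10)
})

test_that("concentration addition is additive and homogeneous", {
    reg <- toyRegistry()
    eff <- toyEffects("activation")
    a <- c(pcb153 = 100)
    b <- c(pcb138 = 50)
    ab <- c(a, b)
    expect_equal(beqChem(ab, eff, reg)$total,
                 beqChem(a, eff, reg)$total + beqChem(b, eff, reg)$total)
    expect_equal(beqChem(3 * ab, eff, reg)$total,
                 3 * beqChem(ab, eff, reg)$total)
    effTu <- toyEffects("cytotoxicity")
    expect_equal(tuChem(5 * ab, effTu, reg)$total,
                 5 * tuChem(ab, effTu, reg)$total)
    ## no cytotoxic compounds detected -> TU_chem = 0
    expect_equal(tuChem(c(dde = 10), effTu, reg)$total, 0)
})

test_that("explained fraction is the predicted/measured percentage", {
    expect_equal(explainedFraction(2, 2), 100)
    expect_equal(explainedFraction(0, 2), 0)
    expect_equal(explainedFraction(3, 2), 150)  # over-explanation reported
    expect_error(explainedFraction(1, 0), "> 0")
})

test_that("volatility classification partitions the registry", {
    reg <- toyRegistry()
    cls <- classifyCompounds(reg, VolatilityRule(1e4))
    expect_equal(unname(cls),
                 c("captured", "captured", "captured", "no_effect_data",
                   "volatile_excluded"))
    ## K exactly at the threshold is not volatile (strict <)
    reg$log_k_medium_air[5] <- 4
    expect_equal(unname(classifyCompounds(reg)[5]), "no_effect_data")
    ## missing K -> non-volatile with a warning
    reg$log_k_medium_air[5] <- NA
    expect_warning(cls2 <- classifyCompounds(reg), "non-volatile")
    expect_equal(unname(cls2[5]), "no_effect_data")
})

test_that("burden accounting sums to 100 and matches hand-computed shares", {
    cls <- c(a = "captured", b = "no_effect_data", c = "volatile_excluded")
    fr <- fractionAccounting(c(a = 50, b = 30, c = 20), cls)
    expect_equal(unname(fr), c(50, 30, 20))
    expect_equal(sum(fr), 100, tolerance = 1e-9)
    ## all captured
    fr2 <- fractionAccounting(c(a = 5), cls)
    expect_equal(unname(fr2), c(100, 0, 0))
    expect_error(fractionAccounting(c(a = NA_real_), cls), "no detected")
    expect_error(fractionAccounting(c(z = 1), cls), "classification")
    ## molar basis reweights by molar mass
    reg <- toyRegistry()
    cls3 <- setNames(c("captured", "no_effect_data"),
                     c("pcb153", "flu"))
    fr3 <- fractionAccounting(c(pcb153 = 10, flu = 10), cls3, reg,
                              basis = "molar")
    w <- c(10 / 360.88, 10 / 166.22)
    expect_equal(unname(fr3[1:2]), 100 * w / sum(w))
})

test_that("study-level iceberg run flags semi-quantitative extracts", {
    ct <- censorTable(toyTable())
    st <- statusMatrix(ct)
    st["pcb153", "a1_liver"] <- "above_calibration"
    ct <- toyTable(concMatrix(ct), st)
    bio <- as(DataFrame(
        sample_id = c("a1_liver", "a2_liver"),
        assay = "ahr_calux", endpoint = "activation",
        ec_extract_kg_l = c(1e-4, 2e-4),
        reference_compound = "pcb153",
        ec_reference_mol_l = 2e-8), "BioassayPanel")
    res <- runIceberg(ct, list(toyEffects("activation")), bio)
    expect_s4_class(res, "IcebergResult")
    expect_equal(res$semi_quantitative, c(TRUE, FALSE))
    expect_equal(res$explained_pct,
                 100 * res$predicted / res$measured)
    expect_equal(res$fraction_captured_pct +
                     res$fraction_no_effect_data_pct +
                     res$fraction_volatile_pct,
                 rep(100, 2), tolerance = 1e-9)
    ## per-compound contribution maps are attached and consistent
    contribs <- S4Vectors::metadata(res)$contributions
    expect_equal(sum(contribs[["a1_liver.ahr_calux.activation"]]),
                 res$predicted[1])
})
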