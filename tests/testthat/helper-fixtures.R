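## small in-code fixtures shared across test files

suppressPackageStartupMessages({
    library(S4Vectors)
    library(SummarizedExperiment)
})

toyRegistry <- function() {
    df <- DataFrame(
        compound_id = c("pcb153", "pcb138", "flu", "dde", "volat"),
        name = c("PCB153", "PCB138", "fluorene", "4,4'-DDE",
                 "naphthalene"),
        group = c("PCB", "PCB", "PAH", "OCP", "PAH"),
        molar_mass_g_mol = c(360.88, 360.88, 166.22, 318.03, 128.17),
        mdl_pg_mg = c(2, 2, 1, 1.5, 1),
        k_lipid_pdms = c(25, 21, NA, 30, NA),
        log_kow = c(6.9, 6.8, 4.2, 6.5, 3.3),
        log_k_medium_air = c(7.5, 7.4, 5.0, 6.8, 3.0),
        effect_tested = c(TRUE, TRUE, TRUE, FALSE, FALSE),
        ec_ahr_calux_mol_l = c(2e-8, 5e-8, NA, NA, NA),
        ic_ahr_calux_mol_l = c(1e-5, NA, 3e-5, NA, NA))
    out <- as(df, "CompoundRegistry")
    rownames(out) <- out$compound_id
    out
}

toySamples <- function() {
    df <- DataFrame(
        sample_id = c("a1_liver", "a1_blubber", "a2_liver", "a2_blubber"),
        animal_id = c("a1", "a1", "a2", "a2"),
        species = rep("harbor_porpoise", 4),
        organ = c("liver", "blubber", "liver", "blubber"),
        lipid_fraction = c(0.05, 0.6, 0.08, 0.5),
        pdms_mass_mg = c(100, 120, 90, 110),
        lipid_uptake_fraction = c(0.01, 0.008, 0.012, 0.009))
    out <- as(df, "SampleTable")
    rownames(out) <- out$sample_id
    out
}

toyTable <- function(conc = NULL, status = NULL) {
    reg <- toyRegistry()
    smp <- toySamples()
    if (is.null(conc)) {
        conc <- matrix(c(
            100, 80, 50, 40,    # pcb153
            60, 50, 30, 25,     # pcb138
            10, NA, 8, 6,       # flu
            40, 90, 20, 70,     # dde
            5, 4, NA, 3),       # volat
            nrow = 5, byrow = TRUE,
            dimnames = list(reg$compound_id, smp$sample_id))
    }
    ConcentrationTable(conc, status, registry = reg, samples = smp)
}

toyEffects <- function(endpoint = "activation") {
    effectDatasetFromRegistry(toyRegistry(), "ahr_calux", endpoint,
                              referenceCompound = "pcb153")
}

## independent published two-tailed 99% Student-t quantiles, df 2..9
T_TABLE_995 <- c(`2` = 9.925, `3` = 5.841, `4` = 4.604, `5` = 4.032,
                 `6` = 3.707, `7` = 3.499, `8` = 3.355, `9` = 3.250)

smallConfig <- function(...) {
    SynthConfig(nAnimals = 4, fullOrganAnimals = 4, highBurdenAnimal = 0,
                nCompounds = 40, bioassayAnimals = 3, ...)
}
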