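eps <- 1e-9

test_that("RU breakpoints assign the boundary to the upper category", {
    # ERBB2: Negative < -0.7 <= Equivocal < 0 <= Positive
    expect_equal(classifyRU("ERBB2", c(-0.7 - eps, -0.7, -eps, 0)),
                 c("Negative", "Equivocal", "Equivocal", "Positive"))
    # ESR1: Negative < 0 <= Low Positive < 1.1 <= High Positive
    expect_equal(classifyRU("ESR1", c(-eps, 0, 1.1 - eps, 1.1)),
                 c("Negative", "Low Positive", "Low Positive",
                   "High Positive"))
    # PGR boundaries at 0 and 0.5
    expect_equal(classifyRU("PGR", c(-eps, 0, 0.5 - eps, 0.5)),
                 c("Negative", "Low Positive", "Low Positive",
                   "High Positive"))
    # MKI67 boundary at 0
    expect_equal(classifyRU("MKI67", c(-eps, 0)), c("Low", "High"))
    expect_error(classifyRU("TP53", 0), "no thresholds")
    expect_error(classifyRU("ESR1", Inf), "finite")
})

test_that("IHC percentage breakpoints match the RU category equivalents", {
    expect_equal(classifyIHCPercent("ER", c(0, 1 - eps, 1, 50 - eps, 50)),
                 c("Negative", "Negative", "Low Positive", "Low Positive",
                   "High Positive"))
    expect_equal(classifyIHCPercent("PR", c(0.9, 1, 19, 20)),
                 c("Negative", "Low Positive", "Low Positive",
                   "High Positive"))
    expect_equal(classifyIHCPercent("Ki67", c(19.9, 20)), c("Low", "High"))
    expect_error(classifyIHCPercent("ER", 101), "\\[0, 100\\]")
    expect_error(classifyIHCPercent("ER", -0.1), "\\[0, 100\\]")
    expect_error(classifyIHCPercent("HER2", 10), "ER, PR, Ki67")
})

test_that("every finite input maps to exactly one category (dense grid)", {
    thr <- markerThresholds()
    ru_grid <- seq(-5, 5, by = 0.01)
    for (g in targetGenes()) {
        cats <- classifyRU(g, ru_grid)
        expect_false(anyNA(cats))
        expect_true(all(cats %in% thr[[g]]$ru$labels))
    }
    pct_grid <- seq(0, 100, by = 0.25)
    for (mk in c("ER", "PR", "Ki67")) {
        cats <- classifyIHCPercent(mk, pct_grid)
        expect_false(anyNA(cats))
    }
    # equivocal rescue: an ERBB2 RU in [-0.7, 0) is never Negative
    zone <- seq(-0.7, -1e-6, length.out = 200)
    expect_true(all(classifyRU("ERBB2", zone) == "Equivocal"))
})

test_that("HER2 IHC ordinal scores map to the three nominal categories", {
    expect_equal(classifyHER2IHC(c("0", "1+", "2+", "3+")),
                 c("Negative", "Negative", "Equivocal", "Positive"))
    expect_error(classifyHER2IHC("4+"), "unknown HER2")
})

test_that("dual-probe FISH follows the 2013 ASCO/CAP rules", {
    expect_equal(as.character(classifyFISH(2.0, 3.0)), "Positive")
    expect_equal(as.character(classifyFISH(1.5, 4.0)), "Equivocal")
    expect_equal(as.character(classifyFISH(1.2, 3.9)), "Negative")
    expect_equal(as.character(classifyFISH(1.2, 6.0)), "Positive")
    expect_equal(as.character(classifyFISH(1.9, 5.99)), "Equivocal")
    expect_equal(attr(classifyFISH(1, 1), "guideline"), "ASCO/CAP 2013")
    expect_error(classifyFISH(NA, 4), "required")
    expect_error(classifyFISH(0, 4), "> 0")
})

test_that("resolveHER2 applies the reflex-FISH algorithm", {
    expect_equal(resolveHER2("3+"), "Positive")
    expect_equal(resolveHER2("0"), "Negative")
    expect_equal(resolveHER2("1+"), "Negative")
    expect_equal(resolveHER2("2+", "Positive"), "Positive")
    expect_equal(resolveHER2("2+", "Negative"), "Negative")
    expect_equal(resolveHER2("2+", "Equivocal"), "Equivocal")
    expect_equal(resolveHER2("2+"), "Equivocal-unresolved")
    # a supplied FISH Positive/Negative always resolves a 2+
    out <- resolveHER2(rep("2+", 50),
                       rep(c("Positive", "Negative"), 25))
    expect_false(any(grepl("Equivocal", out)))
    # FISH never overrides an unequivocal IHC score
    expect_equal(resolveHER2("3+", "Negative"), "Positive")
})

test_that("ki67Zone splits at 9 and 30 with an inclusive intermediate band", {
    expect_equal(ki67Zone(c(5.5, 9 - eps, 9, 15, 30, 30 + eps, 33.5)),
                 c("Low", "Low", "Intermediate", "Intermediate",
                   "Intermediate", "High", "High"))
    expect_error(ki67Zone(120), "\\[0, 100\\]")
})

test_that("the shipped YAML registry matches the built-in thresholds", {
    shipped <- system.file("extdata", "thresholds.yaml",
                           package = "brcaConcord")
    thr <- markerThresholds(shipped)
    ref <- markerThresholds()
    for (g in targetGenes()) {
        expect_equal(thr[[g]]$ru$breaks, ref[[g]]$ru$breaks)
        expect_equal(thr[[g]]$ru$labels, ref[[g]]$ru$labels)
    }
})

test_that("threshold registry round-trips through YAML and validates order", {
    path <- withr::local_tempfile(fileext = ".yaml")
    writeThresholds(path)
    thr <- markerThresholds(path)
    expect_equal(thr$ERBB2$ru$breaks, c(-0.7, 0))
    expect_equal(classifyRU("ESR1", 1.1, thr), "High Positive")
    bad <- markerThresholds()
    bad$ESR1$ru$breaks <- c(1.1, 0)
    yaml::write_yaml(bad, path)
    expect_error(markerThresholds(path), "strictly increasing")
})
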