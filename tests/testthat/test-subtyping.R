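test_that("surrogate subtype rules cover the canonical constellations", {
    # ER+ 80%, PR 30% (High Positive), HER2-, Ki67 10% (Low): Luminal A
    expect_equal(as.character(assignSubtype(
        classifyIHCPercent("ER", 80), classifyIHCPercent("PR", 30),
        "Negative", classifyIHCPercent("Ki67", 10))),
        "Luminal A-like")
    # same but Ki67 25% (High): Luminal B (HER2-)
    expect_equal(as.character(assignSubtype(
        classifyIHCPercent("ER", 80), classifyIHCPercent("PR", 30),
        "Negative", classifyIHCPercent("Ki67", 25))),
        "Luminal B-like (HER2-)")
    # PR below the 20% criterion blocks Luminal A even with low Ki67
    expect_equal(as.character(assignSubtype(
        "High Positive", "Low Positive", "Negative", "Low")),
        "Luminal B-like (HER2-)")
    # ...unless the PR criterion is switched off
    expect_equal(as.character(assignSubtype(
        "High Positive", "Low Positive", "Negative", "Low",
        require_pr_high = FALSE)),
        "Luminal A-like")
    # HER2-driven classes
    expect_equal(as.character(assignSubtype(
        "High Positive", "Negative", "Positive", "High")),
        "Luminal B-like (HER2+)")
    expect_equal(as.character(assignSubtype(
        "Negative", "Negative", "Positive", "High")),
        "HER2-positive (non-luminal)")
    # ER 0%, PR 0%, HER2-, Ki67 40%: triple negative
    expect_equal(as.character(assignSubtype(
        classifyIHCPercent("ER", 0), classifyIHCPercent("PR", 0),
        "Negative", classifyIHCPercent("Ki67", 40))),
        "Triple-negative")
})

test_that("ER-negative/PR-positive tumors are assigned luminal and flagged", {
    st <- assignSubtype("Negative", "High Positive", "Negative", "Low")
    expect_equal(as.character(st), "Luminal B-like (HER2-)")
    expect_true(attr(st, "flagged"))
    st2 <- assignSubtype("Negative", "Low Positive", "Positive", "High")
    expect_equal(as.character(st2), "Luminal B-like (HER2+)")
    expect_true(attr(st2, "flagged"))
    expect_false(attr(assignSubtype("High Positive", "Negative",
                                    "Negative", "High"), "flagged"))
})

test_that("unresolved HER2 is rejected with guidance, not classified", {
    expect_error(assignSubtype("High Positive", "High Positive",
                               "Equivocal-unresolved", "Low"),
                 "resolveHER2")
    expect_error(assignSubtype("High Positive", "High Positive",
                               "Equivocal", "Low"), "resolveHER2")
})

test_that("subtyping is total and deterministic over all input combinations", {
    grid <- expand.grid(
        er = c("Negative", "Low Positive", "High Positive"),
        pr = c("Negative", "Low Positive", "High Positive"),
        her2 = c("Negative", "Positive"),
        ki67 = c("Low", "High"), stringsAsFactors = FALSE)
    s1 <- assignSubtype(grid$er, grid$pr, grid$her2, grid$ki67)
    s2 <- assignSubtype(grid$er, grid$pr, grid$her2, grid$ki67)
    expect_identical(as.character(s1), as.character(s2))
    expect_true(all(s1 %in% subtypeLevels()))
    expect_false(anyNA(s1))
    expect_equal(length(s1), nrow(grid))
})

test_that("a Ki67-only perturbation moves cases only between luminal A and B", {
    er <- rep("High Positive", 20)
    pr <- rep("High Positive", 20)
    her2 <- rep("Negative", 20)
    ki_low <- rep("Low", 20)
    ki_flip <- rep(c("Low", "High"), 10)
    before <- as.character(assignSubtype(er, pr, her2, ki_low))
    after <- as.character(assignSubtype(er, pr, her2, ki_flip))
    moved <- before != after
    expect_true(all(before[moved] == "Luminal A-like"))
    expect_true(all(after[moved] == "Luminal B-like (HER2-)"))
    expect_false(any(after %in% c("Luminal B-like (HER2+)",
                                  "HER2-positive (non-luminal)",
                                  "Triple-negative")))
})

test_that("redistribution cross-tab and switch rates follow the definition", {
    ref <- rep(c("Luminal A-like", "Triple-negative"), c(38, 10))
    alt <- c(rep("Luminal A-like", 29), rep("Luminal B-like (HER2-)", 9),
             rep("Triple-negative", 10))
    r <- redistribution(ref, alt)
    expect_equal(sum(r$table), 48)
    sr <- r$switch_rates
    a_row <- sr[sr$subtype == "Luminal A-like", ]
    expect_equal(a_row$n_ref, 38L)
    expect_equal(a_row$n_switched, 9L)
    expect_equal(a_row$rate, 23.7)  # 9/38, half-up at one decimal
    expect_equal(sr$rate[sr$subtype == "Triple-negative"], 0)
    expect_true(is.na(sr$rate[sr$subtype == "Luminal B-like (HER2+)"]))
    ident <- redistribution(ref, ref)
    expect_equal(sum(diag(ident$table)), 48)
    expect_true(all(ident$switch_rates$rate %in% c(0, NA)))
})
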