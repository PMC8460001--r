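test_that("deltaSummary computes median, absolute-median and SD of |delta|", {
    s <- deltaSummary(c(10, 20, 30), c(12, 18, 35))
    expect_equal(s$median_delta, -2)
    expect_equal(s$median_abs_delta, 2)
    expect_equal(s$sd_abs_delta, sqrt(3))  # sd of (2, 2, 5)
    ident <- deltaSummary(c(1, 5, 9), c(1, 5, 9))
    expect_equal(unlist(ident[1:3]), c(median_delta = 0,
                                       median_abs_delta = 0,
                                       sd_abs_delta = 0))
    shift <- deltaSummary(c(1, 5, 9), c(1, 5, 9) + 5)
    expect_equal(shift$median_delta, -5)
    expect_equal(shift$median_abs_delta, 5)
    expect_equal(shift$sd_abs_delta, 0)
    expect_error(deltaSummary(1:3, 1:4), "equal length")
})

test_that("one-way ICC matches the frozen hand-computed toy value", {
    # 4-case, 2-method toy matrix: MSB = 342.3333..., MSW = 2.25
    est <- iccOneWay(c(10, 20, 30, 40), c(12, 18, 33, 41))
    expect_equal(est$ms_between, 1027 / 3, tolerance = 1e-12)
    expect_equal(est$ms_within, 2.25, tolerance = 1e-12)
    expect_equal(est$icc, 0.986940749698, tolerance = 1e-9)
    expect_true(is.na(est$flag))
})

test_that("ICC edge behaviour: duplicated column, zero variance, negatives", {
    a <- c(3, 7, 1, 9)
    expect_equal(iccOneWay(a, a)$icc, 1)
    z <- iccOneWay(c(5, 5), c(5, 5))
    expect_true(is.na(z$icc))
    expect_equal(z$flag, "zero-variance")
    # anti-correlated pairs push the estimate negative; it is not clamped
    neg <- iccOneWay(c(1, 2, 1, 2), c(2, 1, 2, 1))
    expect_lt(neg$icc, 0)
    expect_equal(neg$flag, "negative")
})

test_that("ICC and Pearson agree with independent oracles on random fixtures", {
    set.seed(42)
    for (i in 1:25) {
        n <- sample(4:30, 1)
        a <- rnorm(n, 50, 20)
        b <- a + rnorm(n, 0, sample(c(1, 5, 15), 1))
        expect_equal(iccOneWay(a, b)$icc, oracleICC(a, b),
                     tolerance = 1e-12)
        expect_equal(pearsonR(a, b)$r, oraclePearson(a, b),
                     tolerance = 1e-12)
    }
})

test_that("ICC of two independent noise columns is near zero at large n", {
    set.seed(7)
    a <- rnorm(5000); b <- rnorm(5000)
    expect_lt(abs(iccOneWay(a, b)$icc), 0.03)
})

test_that("pearsonR handles exact linear relations and degenerate input", {
    a <- c(1, 4, 9, 16, 25)
    expect_equal(pearsonR(a, 2 * a + 1)$r, 1)
    expect_equal(pearsonR(a, -a)$r, -1)
    b <- c(3, 1, 4, 1, 5)
    expect_equal(pearsonR(a, b)$r, oraclePearson(a, b), tolerance = 1e-12)
    z <- pearsonR(a, rep(2, 5))
    expect_true(is.na(z$r))
    expect_equal(z$flag, "zero-variance")
})

test_that("blandAltman flags strictly-greater-than-threshold differences", {
    ba <- blandAltman(c(10, 30, 5), c(25, 40, 5))
    expect_equal(ba$difference, c(-15, -10, 0))
    expect_equal(ba$mean, c(17.5, 35, 5))
    expect_equal(ba$flagged, c(TRUE, FALSE, FALSE))  # 10 is NOT flagged
    expect_equal(sum(blandAltman(1:9, 1:9)$flagged), 0)
})

test_that("discordanceRate reports half-up rounded percentages", {
    mk <- function(k, n) list(a = rep("x", n),
                              b = rep(c("y", "x"), c(k, n - k)))
    for (case in list(c(17, 17.7), c(22, 22.9), c(30, 31.3),
                      c(34, 35.4), c(26, 27.1), c(28, 29.2))) {
        v <- mk(case[1], 96)
        d <- discordanceRate(v$a, v$b)
        expect_equal(d$n_discordant, case[1])
        expect_equal(d$rate, case[2])
    }
    same <- discordanceRate(letters, letters)
    expect_equal(same$n_discordant, 0)
    expect_equal(same$rate, 0)
})

test_that("roundHalfUp rounds halves away from zero", {
    expect_equal(roundHalfUp(31.25), 31.3)   # round() would give 31.2
    expect_equal(roundHalfUp(-31.25), -31.3)
    expect_equal(roundHalfUp(29.1666667), 29.2)
    expect_equal(roundHalfUp(2.5, 0), 3)
})

test_that("unionDiscordant applies inclusion-exclusion with validation", {
    expect_equal(unionDiscordant(17, 15, 10), 22L)
    expect_equal(unionDiscordant(5, 5, 0), 10L)
    expect_equal(unionDiscordant(7, 7, 7), 7L)
    expect_error(unionDiscordant(5, 5, 6), "inconsistent overlap")
})

test_that("rateByZone recovers per-zone rates and preserves the overall rate", {
    zones <- rep(c("Low", "Intermediate", "High"), c(10, 9, 5))
    disc <- rep(FALSE, 24)
    disc[11:14] <- TRUE  # 4 of 9 intermediate cases discordant
    rz <- rateByZone(zones, disc, levels = c("Low", "Intermediate", "High"))
    expect_equal(rz$rate, c(0, 44.4, 0))
    # weighted zone average equals the overall discordance rate
    overall <- sum(rz$n_discordant) / sum(rz$n)
    expect_equal(sum(rz$rate_raw * rz$n) / (100 * sum(rz$n)), overall)
    # empty zone reports NA
    rz2 <- rateByZone(zones, disc,
                      levels = c("Low", "Intermediate", "High", "Void"))
    expect_true(is.na(rz2$rate[4]))
})

test_that("rateByZone recovers generator-set zone discordance probabilities", {
    set.seed(123)
    p <- c(Low = 0.05, Intermediate = 0.45, High = 0.05)
    zones <- sample(names(p), 4000, replace = TRUE)
    disc <- runif(4000) < p[zones]
    rz <- rateByZone(zones, disc, levels = names(p))
    # binomial error at n ~ 1300 per zone: 3 sd ~ 4 points
    expect_true(all(abs(rz$rate_raw - 100 * p[rz$zone]) < 4))
})

test_that("crossTab conserves marginals and matches a hand tally", {
    a <- c("N", "N", "P", "P", "E", "N")
    b <- c("N", "P", "P", "P", "E", "N")
    tab <- crossTab(a, b, levels = c("N", "E", "P"))
    expect_equal(sum(tab), 6)
    expect_equal(as.vector(rowSums(tab)), c(3, 1, 2))
    expect_equal(as.vector(colSums(tab)), c(2, 1, 3))
    expect_equal(tab["N", "N"], 2)
    expect_equal(tab["N", "P"], 1)
    expect_equal(tab["P", "P"], 2)
    ident <- crossTab(a, a)
    expect_equal(sum(diag(ident)), 6)
})

test_that("agreement statistics are symmetric where they should be", {
    set.seed(9)
    a <- rnorm(40, 30, 10); b <- a + rnorm(40, 0, 5)
    expect_equal(iccOneWay(a, b)$icc, iccOneWay(b, a)$icc)
    expect_equal(pearsonR(a, b)$r, pearsonR(b, a)$r)
    ca <- sample(c("x", "y"), 40, TRUE); cb <- sample(c("x", "y"), 40, TRUE)
    expect_equal(discordanceRate(ca, cb)$rate, discordanceRate(cb, ca)$rate)
    # delta statistics flip sign with order, |delta| ones do not
    expect_equal(deltaSummary(a, b)$median_delta,
                 -deltaSummary(b, a)$median_delta)
    expect_equal(deltaSummary(a, b)$median_abs_delta,
                 deltaSummary(b, a)$median_abs_delta)
})

test_that("compareRates reproduces a two-proportion chi-square test", {
    ht <- compareRates(19, 43, 3, 44)
    ref <- stats::prop.test(c(19, 3), c(43, 44))
    expect_equal(ht$p_value, ref$p.value)
    expect_lt(ht$p_value, 0.05)
})
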