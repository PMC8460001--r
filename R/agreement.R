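## Paired-method agreement statistics: difference summaries, one-way
## random-effects ICC, Pearson correlation, Bland-Altman flagging,
## categorical discordance accounting and its zone breakdown.
## Sign convention throughout: delta = first method - second method
## (conventionally ORI - REV or ORI - DIA).

.checkPair <- function(a, b, min_n = 1L) {
    if (length(a) != length(b))
        stop("paired vectors must have equal length", call. = FALSE)
    if (length(a) < min_n)
        stop("at least ", min_n, " aligned pairs required", call. = FALSE)
    invisible(TRUE)
}

#' Round half away from zero
#'
#' Reporting convention for percentages: rounds halves up (e.g. 31.25 to
#' 31.3 at one decimal), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(100 * 30 / 96, 1)  # 31.3
#' @export
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Paired difference summary
#'
#' Median difference, median absolute difference and the sample standard
#' deviation of the absolute differences for two aligned score vectors,
#' with delta defined as `a - b`.
#'
#' @param a,b aligned numeric vectors (first method minus second).
#' @return list with `median_delta`, `median_abs_delta`, `sd_abs_delta`,
#'   `n`.
#' @examples
#' deltaSummary(c(10, 20, 30), c(12, 18, 35))
#' @export
deltaSummary <- function(a, b) {
    .checkPair(a, b, 1L)
    d <- a - b
    list(median_delta = stats::median(d),
         median_abs_delta = stats::median(abs(d)),
         sd_abs_delta = if (length(d) > 1L) stats::sd(abs(d)) else 0,
         n = length(d))
}

#' One-way random-effects intraclass correlation
#'
#' Estimates the ICC as between-case variance over total variance via the
#' one-way random-effects ANOVA decomposition (ICC(1,1)):
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` with cases as the random grouping
#' and the k methods as exchangeable replicate measurements. Negative
#' estimates are returned as-is and flagged, not clamped; a matrix with no
#' variability at all yields `NA` with a `"zero-variance"` flag.
#'
#' @param a,b aligned numeric vectors, or give `m` directly.
#' @param m optional numeric matrix (cases in rows, methods in columns,
#'   k >= 2); overrides `a`/`b`.
#' @return list with `icc`, `ms_between`, `ms_within`, `n`, `k` and
#'   `flag` (`NA_character_` when the estimate is unremarkable).
#' @examples
#' iccOneWay(c(10, 20, 30, 40), c(12, 18, 33, 41))
#' @export
iccOneWay <- function(a = NULL, b = NULL, m = NULL) {
    if (is.null(m)) {
        .checkPair(a, b, 2L)
        m <- cbind(a, b)
    }
    m <- as.matrix(m)
    n <- nrow(m); k <- ncol(m)
    if (n < 2L || k < 2L)
        stop("ICC needs at least 2 cases and 2 methods", call. = FALSE)
    grand <- mean(m)
    case_means <- rowMeans(m)
    msb <- k * sum((case_means - grand)^2) / (n - 1)
    msw <- sum((m - case_means)^2) / (n * (k - 1))
    tot <- sum((m - grand)^2)
    if (tot == 0)
        return(list(icc = NA_real_, ms_between = msb, ms_within = msw,
                    n = n, k = k, flag = "zero-variance"))
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    list(icc = icc, ms_between = msb, ms_within = msw, n = n, k = k,
         flag = if (icc < 0) "negative" else NA_character_)
}

#' Pearson correlation with zero-variance guard
#'
#' Standard product-moment correlation via [stats::cor()]; a degenerate
#' vector (zero variance) yields `NA` with a flag instead of an error.
#'
#' @param a,b aligned numeric vectors (n >= 2).
#' @return list with `r`, `n`, `flag`.
#' @export
pearsonR <- function(a, b) {
    .checkPair(a, b, 2L)
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        return(list(r = NA_real_, n = length(a), flag = "zero-variance"))
    list(r = stats::cor(a, b), n = length(a), flag = NA_character_)
}

#' Bland-Altman differences with threshold flagging
#'
#' Per-case mean `(a + b) / 2` and difference `a - b`; a case is flagged
#' when its absolute difference strictly exceeds the threshold ("differed
#' by more than 10 percent" is strict, so a difference of exactly 10 is
#' not flagged).
#'
#' @param a,b aligned numeric vectors.
#' @param threshold flagging threshold in the score's units (default 10
#'   percentage points).
#' @param case_ids optional identifiers.
#' @return `data.frame` with `case_id`, `mean`, `difference`, `flagged`.
#' @examples
#' blandAltman(c(10, 30), c(25, 40))
#' @export
blandAltman <- function(a, b, threshold = 10, case_ids = seq_along(a)) {
    .checkPair(a, b, 1L)
    data.frame(case_id = case_ids,
               mean = (a + b) / 2,
               difference = a - b,
               flagged = abs(a - b) > threshold)
}

#' Categorical discordance count and rate
#'
#' Counts positions at which two aligned categorical call vectors differ
#' and reports the percentage, rounded half-up to one decimal in the
#' reporting convention (the raw value is also returned).
#'
#' @param calls_a,calls_b aligned character vectors of category calls.
#' @return list with `n_discordant`, `n`, `rate` (rounded, \%),
#'   `rate_raw` (\%).
#' @examples
#' discordanceRate(rep(c("Low", "High"), c(79, 17)), rep("Low", 96))
#' @export
discordanceRate <- function(calls_a, calls_b) {
    .checkPair(calls_a, calls_b, 1L)
    n <- length(calls_a)
    cnt <- sum(calls_a != calls_b)
    raw <- 100 * cnt / n
    list(n_discordant = cnt, n = n, rate = roundHalfUp(raw, 1),
         rate_raw = raw)
}

#' Union of discordant-case sets by inclusion-exclusion
#'
#' Given the number of cases discordant under method A, under method B
#' (both as inclusive totals) and under both, returns the number
#' discordant under at least one: `|A| + |B| - |A and B|`.
#'
#' @param n_a,n_b inclusive per-method discordant counts.
#' @param n_both size of the overlap.
#' @return integer count of the union.
#' @examples
#' unionDiscordant(17, 15, 10)  # 22
#' @export
unionDiscordant <- function(n_a, n_b, n_both) {
    if (n_both > min(n_a, n_b) || any(c(n_a, n_b, n_both) < 0))
        stop("inconsistent overlap: need 0 <= n_both <= min(n_a, n_b)",
             call. = FALSE)
    as.integer(n_a + n_b - n_both)
}

#' Discordance rate within zones
#'
#' Breaks an aligned discordance-flag vector down by zone (e.g. the
#' Low/Intermediate/High Ki67 zones) and reports per-zone counts and
#' percentages. An empty zone's rate is `NA`.
#'
#' @param zones character or factor vector of zone labels.
#' @param discordant logical vector, aligned with `zones`.
#' @param levels optional zone ordering (defaults to order of appearance,
#'   or factor levels).
#' @return `data.frame` with `zone`, `n`, `n_discordant`, `rate` (\%,
#'   rounded half-up to one decimal) and `rate_raw`.
#' @export
rateByZone <- function(zones, discordant, levels = NULL) {
    .checkPair(zones, discordant, 1L)
    if (is.null(levels))
        levels <- if (is.factor(zones)) base::levels(zones) else unique(zones)
    zones <- factor(zones, levels = levels)
    n <- tabulate(zones, nbins = nlevels(zones))
    nd <- vapply(seq_len(nlevels(zones)), function(i)
        sum(discordant[as.integer(zones) == i]), integer(1))
    raw <- ifelse(n > 0, 100 * nd / n, NA_real_)
    data.frame(zone = levels, n = n, n_discordant = nd,
               rate = roundHalfUp(raw, 1), rate_raw = raw)
}

#' Category cross-tabulation
#'
#' Contingency table of two aligned categorical call vectors; marginals
#' equal the input totals. A shared level set keeps the table square.
#'
#' @param calls_a,calls_b aligned character vectors.
#' @param levels optional shared category levels.
#' @return a [table].
#' @export
crossTab <- function(calls_a, calls_b, levels = NULL) {
    .checkPair(calls_a, calls_b, 1L)
    if (is.null(levels))
        levels <- union(unique(calls_a), unique(calls_b))
    table(a = factor(calls_a, levels = levels),
          b = factor(calls_b, levels = levels))
}

#' Compare two discordance proportions
#'
#' Two-proportion chi-square test (via [stats::prop.test()]) for claims of
#' the form "discordance was higher in one zone than another". No
#' multiple-testing correction is applied.
#'
#' @param x1,n1 discordant count and total in group 1.
#' @param x2,n2 discordant count and total in group 2.
#' @param correct continuity correction (default TRUE, as in
#'   [stats::prop.test()]).
#' @return list with `p_value`, `estimate` (two proportions), `method`.
#' @export
compareRates <- function(x1, n1, x2, n2, correct = TRUE) {
    ht <- stats::prop.test(c(x1, x2), c(n1, n2), correct = correct)
    list(p_value = ht$p.value, estimate = unname(ht$estimate),
         method = ht$method)
}

#' Full paired-method agreement summary
#'
#' Combines the continuous agreement statistics for one marker and method
#' pair into a single row: difference summary, ICC, Pearson correlation
#' and the count and rate of cases differing by more than the
#' Bland-Altman threshold.
#'
#' @param a,b aligned numeric score vectors (first method minus second
#'   for the delta columns).
#' @param threshold Bland-Altman flag threshold (default 10).
#' @return one-row `data.frame` with columns `n`, `median_delta`,
#'   `median_abs_delta`, `sd_abs_delta`, `icc`, `pearson_r`,
#'   `n_over_threshold`, `rate_over_threshold`.
#' @export
agreementSummary <- function(a, b, threshold = 10) {
    ds <- deltaSummary(a, b)
    icc <- iccOneWay(a, b)
    pr <- pearsonR(a, b)
    ba <- blandAltman(a, b, threshold = threshold)
    nflag <- sum(ba$flagged)
    data.frame(n = ds$n,
               median_delta = ds$median_delta,
               median_abs_delta = ds$median_abs_delta,
               sd_abs_delta = ds$sd_abs_delta,
               icc = icc$icc,
               pearson_r = pr$r,
               n_over_threshold = nflag,
               rate_over_threshold = roundHalfUp(100 * nflag / ds$n, 1))
}
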