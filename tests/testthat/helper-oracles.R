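# Independent oracles used to cross-check the agreement statistics.
# Deliberately implemented through different routes than the package:
# the ICC oracle goes through R's ANOVA machinery (stats::aov), the
# Pearson oracle through the raw covariance formula.

oracleICC <- function(a, b) {
    d <- data.frame(y = c(a, b),
                    case = factor(rep(seq_along(a), 2)))
    ms <- summary(stats::aov(y ~ case, data = d))[[1]][["Mean Sq"]]
    msb <- ms[1]; msw <- ms[2]
    k <- 2
    (msb - msw) / (msb + (k - 1) * msw)
}

oraclePearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Minimal two-run CqRunSet: one target gene, optional reference genes.
# Scalar Cqs are duplicated so the fixtures carry >= 2 replicates.
makeRuns <- function(target_cq, cal_cq, ref_cq = c(B2M = 26),
                     cal_ref_cq = ref_cq, gene = "ESR1") {
    row <- function(sid, g, role, cq) {
        if (length(cq) == 1L) cq <- rep(cq, 2L)
        data.frame(sample_id = sid, gene_id = g, role = role,
                   replicate = seq_along(cq), cq = cq)
    }
    df <- rbind(
        row("S1", gene, "target", target_cq),
        do.call(rbind, lapply(names(ref_cq), function(r)
            row("S1", r, "reference", ref_cq[[r]]))),
        row("PC", gene, "target", cal_cq),
        do.call(rbind, lapply(names(cal_ref_cq), function(r)
            row("PC", r, "reference", cal_ref_cq[[r]]))))
    CqRunSet(df, calibrator = "PC")
}
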