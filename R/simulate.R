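## Synthetic paired multi-method cohort generator.
##
## One latent truth per case (marker percentages, a trimodal HER2 state,
## a latent log2 expression level per target gene) feeds every
## measurement channel: three correlated IHC reads with observer noise,
## HER2 ordinal scores with occasional adjacent-category misgrades,
## dual-probe FISH inputs where HER2 status warrants them, and Cq
## replicate panels linked to the latent expression. Generator truth
## labels are, by construction, what the classification module returns
## on the noiseless latent values.

#' Simulation configuration
#'
#' Builds the configuration list for [generateCohort()]. Defaults emulate
#' a ~96-case surgical breast-cancer cohort: bimodal ER (a small
#' negative cluster, about 10/96, plus a broad strongly positive
#' component), a more dispersed PR mixture (about 18/96 negative),
#' right-skewed continuous Ki67 centered in the high teens (about 40\%
#' of cases at or above the 20\% cutoff), and a trimodal HER2 state
#' (negative/equivocal/positive roughly 66/13/17 of 96).
#'
#' @param n_cases cohort size (default 96).
#' @param seed integer seed; per-case substreams are derived from it so
#'   that enlarging the cohort does not reshuffle earlier cases.
#' @param er_mixture,pr_mixture lists with `neg_weight` (probability of
#'   the negative cluster), `pos_shape1`, `pos_shape2` (Beta shape of the
#'   positive component on the 0-100 scale).
#' @param ki67 list with `meanlog`, `sdlog` of the lognormal Ki67
#'   percentage distribution.
#' @param her2_class_probs named probabilities of the latent HER2 state
#'   (`Negative`, `Equivocal`, `Positive`); must sum to 1.
#' @param her2_equiv_resolution probabilities that a latent-equivocal
#'   case is truly `Negative` vs `Positive` on the FISH level.
#' @param observer_noise_sd per-method IHC reading noise, percentage
#'   points (`ORI`, `REV`, `DIA`).
#' @param ori_grid grid (percentage points) the ORI read is snapped to,
#'   mimicking quick eyeballing versus formal counting; applied only
#'   when the ORI observer noise is non-zero (the grid snap is part of
#'   the observer-imprecision model). `NULL` disables snapping.
#' @param her2_misgrade_prob per-method probability that the HER2
#'   ordinal score is misread into an adjacent category.
#' @param rev_ki67_shift systematic Ki67 upgrade (percentage points)
#'   added to the REV read before noise — used to plant the
#'   re-evaluation upgrade effect (default 0).
#' @param cq_link list with per-gene `slope` and `intercept` of the
#'   linear latent-expression-to-Cq link `Cq = intercept - slope * log2
#'   expression`.
#' @param n_replicates Cq replicates per gene per run (default 3).
#' @param replicate_sd Cq replicate noise, cycles (default 0.15).
#' @param reference_cq named baseline Cq per reference gene, cycles.
#' @param raw_cutoffs named per-gene raw cutoffs on the ddCq scale
#'   (known to the generator so that round-trip tests are closed).
#' @param fish list with `borderline_frac`: fraction of FISH results
#'   drawn close to the decision boundaries (on the correct side).
#' @return a validated configuration list of class `"sim_config"`.
#' @export
simConfig <- function(n_cases = 96,
                      seed = 20211L,
                      er_mixture = list(neg_weight = 10 / 96,
                                        pos_shape1 = 4, pos_shape2 = 1.2),
                      pr_mixture = list(neg_weight = 18 / 96,
                                        pos_shape1 = 1.6, pos_shape2 = 1.2),
                      ki67 = list(meanlog = log(16), sdlog = 0.8),
                      her2_class_probs = c(Negative = 66, Equivocal = 13,
                                           Positive = 17) / 96,
                      her2_equiv_resolution = c(Negative = 0.7,
                                                Positive = 0.3),
                      observer_noise_sd = c(ORI = 6, REV = 4, DIA = 4),
                      ori_grid = 5,
                      her2_misgrade_prob = c(ORI = 0.06, REV = 0.03),
                      rev_ki67_shift = 0,
                      cq_link = list(
                          slope = c(ESR1 = 1, PGR = 1, ERBB2 = 1, MKI67 = 1),
                          intercept = c(ESR1 = 30, PGR = 31, ERBB2 = 28,
                                        MKI67 = 29)),
                      n_replicates = 3L,
                      replicate_sd = 0.15,
                      reference_cq = c(B2M = 17, CALM2 = 18),
                      raw_cutoffs = c(ESR1 = 1.0, PGR = 0.5, ERBB2 = 2.0,
                                      MKI67 = 1.5),
                      fish = list(borderline_frac = 0.2)) {
    cfg <- list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                er_mixture = er_mixture, pr_mixture = pr_mixture,
                ki67 = ki67, her2_class_probs = her2_class_probs,
                her2_equiv_resolution = her2_equiv_resolution,
                observer_noise_sd = observer_noise_sd, ori_grid = ori_grid,
                her2_misgrade_prob = her2_misgrade_prob,
                rev_ki67_shift = rev_ki67_shift, cq_link = cq_link,
                n_replicates = as.integer(n_replicates),
                replicate_sd = replicate_sd, reference_cq = reference_cq,
                raw_cutoffs = raw_cutoffs, fish = fish)
    .validateSimConfig(cfg)
    class(cfg) <- "sim_config"
    cfg
}

.validateSimConfig <- function(cfg) {
    if (cfg$n_cases < 1L) stop("n_cases must be >= 1", call. = FALSE)
    if (abs(sum(cfg$her2_class_probs) - 1) > 1e-8)
        stop("her2_class_probs must sum to 1", call. = FALSE)
    if (abs(sum(cfg$her2_equiv_resolution) - 1) > 1e-8)
        stop("her2_equiv_resolution must sum to 1", call. = FALSE)
    w <- c(cfg$er_mixture$neg_weight, cfg$pr_mixture$neg_weight)
    if (any(w < 0 | w > 1))
        stop("mixture negative-cluster weights must lie in [0, 1]",
             call. = FALSE)
    scales <- c(cfg$observer_noise_sd, cfg$replicate_sd,
                cfg$ki67$sdlog, cfg$fish$borderline_frac)
    if (any(scales < 0)) stop("all noise scales must be >= 0", call. = FALSE)
    if (any(cfg$cq_link$slope <= 0))
        stop("cq_link slopes must be > 0 (higher expression, lower Cq)",
             call. = FALSE)
    miss <- setdiff(.TARGET_GENES,
                    Reduce(intersect, list(names(cfg$cq_link$slope),
                                           names(cfg$cq_link$intercept),
                                           names(cfg$raw_cutoffs))))
    if (length(miss))
        stop("cq_link/raw_cutoffs incomplete for: ",
             paste(miss, collapse = ", "), call. = FALSE)
    invisible(TRUE)
}

## Monotone piecewise-linear link between the IHC percentage scale and
## the latent RU scale; exact at the clinical anchors so that percentage
## categories and RU categories agree on the noiseless latent values
## (1% <-> 0 RU and 50% <-> 1.1 RU for ER; 1% <-> 0 and 20% <-> 0.5 for
## PR; 20% <-> 0 for Ki67).
.RU_ANCHORS <- list(
    ESR1  = list(pct = c(0, 1, 50, 100),  ru = c(-3, 0, 1.1, 2.6)),
    PGR   = list(pct = c(0, 1, 20, 100),  ru = c(-3, 0, 0.5, 2.2)),
    MKI67 = list(pct = c(0, 20, 100),     ru = c(-2.5, 0, 2.5)))

#' Latent link between IHC percentage and RU scales
#'
#' The generator's monotone piecewise-linear mapping from a marker's
#' percentage scale to its relative-units scale, exact at the clinical
#' decision anchors so the two category systems agree on latent values.
#'
#' @param gene_id "ESR1", "PGR" or "MKI67".
#' @param percent percentage values in [0, 100].
#' @return latent RU values.
#' @export
percentToRU <- function(gene_id, percent) {
    a <- .RU_ANCHORS[[gene_id]]
    if (is.null(a))
        stop("no percentage/RU link for gene '", gene_id, "'", call. = FALSE)
    stats::approx(a$pct, a$ru, xout = percent, rule = 2)$y
}

#' Emit Cq replicates for a latent expression level
#'
#' Linear link from latent log2 expression to the quantification cycle:
#' `Cq = intercept - slope * latent + noise`, slope positive so higher
#' expression yields lower Cq. Noise is drawn from the current RNG
#' state.
#'
#' @param latent latent log2 expression value (finite scalar).
#' @param gene_id target gene id (indexes `cq_link` in `config`).
#' @param config a [simConfig()] list.
#' @param n_replicates number of replicates (default from `config`).
#' @return numeric vector of replicate Cq values.
#' @examples
#' cfg <- simConfig(replicate_sd = 0)
#' emitCq(2, "ESR1", cfg) - emitCq(3, "ESR1", cfg)  # +1 latent -> -1 Cq
#' @export
emitCq <- function(latent, gene_id, config,
                   n_replicates = config$n_replicates) {
    stopifnot(is.finite(latent))
    a <- config$cq_link$intercept[[gene_id]]
    b <- config$cq_link$slope[[gene_id]]
    a - b * latent + stats::rnorm(n_replicates, 0, config$replicate_sd)
}

## Per-case deterministic RNG substream: adding cases never reshuffles
## earlier ones. Kept below 2^31 - 1.
.caseSeed <- function(seed, i) {
    as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483647)
}

.clip01 <- function(x) pmin(100, pmax(0, x))

.drawMixturePct <- function(mix) {
    if (stats::runif(1) < mix$neg_weight)
        stats::runif(1, 0, 0.9)
    else
        100 * stats::rbeta(1, mix$pos_shape1, mix$pos_shape2)
}

.misgradeOrdinal <- function(score, prob) {
    lev <- c("0", "1+", "2+", "3+")
    i <- match(score, lev)
    if (stats::runif(1) < prob) {
        step <- if (stats::runif(1) < 0.5) -1L else 1L
        i <- min(max(i + step, 1L), 4L)
    }
    lev[i]
}

.drawFish <- function(truth, borderline_frac) {
    borderline <- stats::runif(1) < borderline_frac
    if (truth == "Positive") {
        if (borderline)
            c(ratio = stats::runif(1, 2.0, 2.3),
              copies = stats::runif(1, 4.0, 5.5))
        else
            c(ratio = stats::runif(1, 2.5, 6.0),
              copies = stats::runif(1, 6.0, 14.0))
    } else {
        if (borderline)
            c(ratio = stats::runif(1, 1.6, 1.95),
              copies = stats::runif(1, 3.0, 3.95))
        else
            c(ratio = stats::runif(1, 0.8, 1.5),
              copies = stats::runif(1, 1.5, 3.5))
    }
}

#' Generate a synthetic paired multi-method cohort
#'
#' Draws latent truth per case, then produces every downstream
#' measurement: ORI/REV/DIA IHC percentage reads for ER, PR and Ki67
#' (ORI optionally snapped to an eyeballing grid), HER2 IHC ordinal
#' scores for ORI and REV (no digital HER2 read, matching routine
#' practice), dual-probe FISH inputs for every latent-equivocal case and
#' every case scored 2+ by any observer, and a full Cq replicate panel
#' per case plus one positive-control run (sample id `"POS_CTRL"`)
#' whose latent expression is zero for every target gene.
#'
#' Generator truth labels (`truth_*` columns) are the classification
#' module's output on the noiseless latent values, so with all noise
#' parameters at zero the full pipeline reproduces them exactly.
#'
#' @param config a [simConfig()] configuration.
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(simConfig(n_cases = 10, seed = 7))
#' head(caseTable(coh))
#' @export
generateCohort <- function(config = simConfig()) {
    .validateSimConfig(config)
    n <- config$n_cases
    rows <- vector("list", n)
    cq_rows <- vector("list", n + 1L)
    methods3 <- c("ORI", "REV", "DIA")
    for (i in seq_len(n)) {
        set.seed(.caseSeed(config$seed, i))
        cid <- sprintf("case_%03d", i)

        ## latent truth
        er <- .drawMixturePct(config$er_mixture)
        pr <- .drawMixturePct(config$pr_mixture)
        ki67 <- min(95, max(0.5, stats::rlnorm(1, config$ki67$meanlog,
                                               config$ki67$sdlog)))
        her2_class <- sample(names(config$her2_class_probs), 1,
                             prob = config$her2_class_probs)
        erbb2_ru <- switch(her2_class,
            Negative = stats::runif(1, -2.4, -0.75),
            Equivocal = stats::runif(1, -0.68, -0.02),
            Positive = stats::runif(1, 0.1, 2.4))
        her2_truth <- switch(her2_class,
            Negative = "Negative", Positive = "Positive",
            Equivocal = sample(names(config$her2_equiv_resolution), 1,
                               prob = config$her2_equiv_resolution))

        ## IHC percentage reads
        reads <- list()
        for (m in methods3) {
            sd_m <- config$observer_noise_sd[[m]]
            shift <- if (m == "REV") config$rev_ki67_shift else 0
            e <- .clip01(er + stats::rnorm(1, 0, sd_m))
            p <- .clip01(pr + stats::rnorm(1, 0, sd_m))
            k <- .clip01(ki67 + shift + stats::rnorm(1, 0, sd_m))
            if (m == "ORI" && !is.null(config$ori_grid) && sd_m > 0) {
                g <- config$ori_grid
                e <- .clip01(round(e / g) * g)
                p <- .clip01(round(p / g) * g)
                k <- .clip01(round(k / g) * g)
            }
            reads[[m]] <- c(er = e, pr = p, ki67 = k)
        }

        ## HER2 ordinal scores (ORI, REV only; no digital HER2 read)
        her2_ord_truth <- switch(her2_class,
            Negative = sample(c("0", "1+"), 1),
            Equivocal = "2+", Positive = "3+")
        her2_ori <- .misgradeOrdinal(her2_ord_truth,
                                     config$her2_misgrade_prob[["ORI"]])
        her2_rev <- .misgradeOrdinal(her2_ord_truth,
                                     config$her2_misgrade_prob[["REV"]])

        ## FISH wherever warranted
        need_fish <- her2_class == "Equivocal" ||
            her2_ori == "2+" || her2_rev == "2+"
        fish <- if (need_fish)
            .drawFish(her2_truth, config$fish$borderline_frac)
        else c(ratio = NA_real_, copies = NA_real_)

        ## latent log2 expression and Cq panel
        latent_ru <- c(ESR1 = percentToRU("ESR1", er),
                       PGR = percentToRU("PGR", pr),
                       MKI67 = percentToRU("MKI67", ki67),
                       ERBB2 = erbb2_ru)
        expr <- latent_ru[.TARGET_GENES] +
            config$raw_cutoffs[.TARGET_GENES]
        cq_tgt <- lapply(.TARGET_GENES, function(g)
            emitCq(expr[[g]], g, config))
        cq_ref <- lapply(names(config$reference_cq), function(r)
            config$reference_cq[[r]] +
                stats::rnorm(config$n_replicates, 0, config$replicate_sd))
        nr <- config$n_replicates
        cq_rows[[i]] <- data.frame(
            sample_id = cid,
            gene_id = rep(c(.TARGET_GENES, names(config$reference_cq)),
                          each = nr),
            role = rep(c("target", "reference"),
                       c(4L * nr, length(config$reference_cq) * nr)),
            replicate = rep(seq_len(nr),
                            4L + length(config$reference_cq)),
            cq = c(unlist(cq_tgt), unlist(cq_ref)),
            stringsAsFactors = FALSE)

        ## generator truth labels via the classification rules
        truth_er <- classifyIHCPercent("ER", er)
        truth_pr <- classifyIHCPercent("PR", pr)
        truth_ki67 <- classifyIHCPercent("Ki67", ki67)
        truth_subtype <- as.character(
            assignSubtype(truth_er, truth_pr, her2_truth, truth_ki67))

        rows[[i]] <- data.frame(
            case_id = cid,
            latent_er = er, latent_pr = pr, latent_ki67 = ki67,
            latent_erbb2_ru = erbb2_ru,
            er_ORI = reads$ORI[["er"]], er_REV = reads$REV[["er"]],
            er_DIA = reads$DIA[["er"]],
            pr_ORI = reads$ORI[["pr"]], pr_REV = reads$REV[["pr"]],
            pr_DIA = reads$DIA[["pr"]],
            ki67_ORI = reads$ORI[["ki67"]], ki67_REV = reads$REV[["ki67"]],
            ki67_DIA = reads$DIA[["ki67"]],
            her2_ihc_ORI = her2_ori, her2_ihc_REV = her2_rev,
            fish_ratio = fish[["ratio"]], fish_copies = fish[["copies"]],
            truth_her2_class = her2_class,
            truth_her2_status = her2_truth,
            truth_er_cat = truth_er, truth_pr_cat = truth_pr,
            truth_ki67_cat = truth_ki67,
            truth_subtype = truth_subtype,
            stringsAsFactors = FALSE)
    }

    ## positive-control (calibrator) run: latent expression 0 throughout
    set.seed(.caseSeed(config$seed, 0L))
    nr <- config$n_replicates
    cal_tgt <- lapply(.TARGET_GENES, function(g) emitCq(0, g, config))
    cal_ref <- lapply(names(config$reference_cq), function(r)
        config$reference_cq[[r]] + stats::rnorm(nr, 0, config$replicate_sd))
    cq_rows[[n + 1L]] <- data.frame(
        sample_id = "POS_CTRL",
        gene_id = rep(c(.TARGET_GENES, names(config$reference_cq)),
                      each = nr),
        role = rep(c("target", "reference"),
                   c(4L * nr, length(config$reference_cq) * nr)),
        replicate = rep(seq_len(nr), 4L + length(config$reference_cq)),
        cq = c(unlist(cal_tgt), unlist(cal_ref)),
        stringsAsFactors = FALSE)

    new("SyntheticCohort",
        cases = do.call(rbind, rows),
        cqRuns = CqRunSet(do.call(rbind, cq_rows), calibrator = "POS_CTRL"),
        config = unclass(config))
}
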