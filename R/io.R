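## Delimited-text I/O for case tables and long-format Cq tables, and the
## end-to-end pipeline runner. Dialect: comma-separated (tab for .tsv),
## UTF-8, "." decimal separator; percentages always on the 0-100 scale.

.CASE_SCHEMA_TAG <- "# brcaConcord case_table v1"
.CQ_SCHEMA_TAG <- "# brcaConcord cq_table v1"
.PCT_COLS_RE <- "^(er|pr|ki67)_(ORI|REV|DIA)$"

.sepFor <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Write and read case tables
#'
#' A case table holds one row per tumor with per-method per-marker IHC
#' percentages (`er_ORI`, ..., `ki67_DIA`), HER2 ordinal scores
#' (`her2_ihc_ORI`, `her2_ihc_REV`) and FISH inputs (`fish_ratio`,
#' `fish_copies`). Files carry a schema-version header line; the reader
#' refuses files without it, and rejects (with a per-row message) rows
#' whose percentages fall outside [0, 100] or whose `case_id`
#' duplicates an earlier row.
#'
#' @param x case `data.frame` to write.
#' @param path file path; `.tsv`/`.txt` selects tab separation.
#' @param sep overrides the separator inferred from the extension.
#' @return `writeCaseTable()` returns `path` invisibly;
#'   `readCaseTable()` the validated `data.frame`.
#' @export
writeCaseTable <- function(x, path, sep = NULL) {
    sep <- .sepFor(path, sep)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.CASE_SCHEMA_TAG, con)
    utils::write.table(x, con, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCaseTable
#' @export
readCaseTable <- function(path, sep = NULL) {
    sep <- .sepFor(path, sep)
    first <- readLines(path, n = 1L)
    if (!identical(first, .CASE_SCHEMA_TAG))
        stop("not a case table (missing schema header '",
             .CASE_SCHEMA_TAG, "'): ", path, call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sep, skip = 1L,
                            stringsAsFactors = FALSE)
    if (!"case_id" %in% names(df))
        stop("case table must contain a case_id column", call. = FALSE)
    pct_cols <- grep(.PCT_COLS_RE, names(df), value = TRUE)
    bad <- rep(FALSE, nrow(df))
    for (cc in pct_cols) {
        v <- df[[cc]]
        out_of_range <- !is.na(v) & (v < 0 | v > 100)
        if (any(out_of_range))
            warning("rejecting row(s) ",
                    paste(which(out_of_range) + 2L, collapse = ", "),
                    " of ", basename(path), ": ", cc,
                    " outside [0, 100]", call. = FALSE)
        bad <- bad | out_of_range
    }
    dup <- duplicated(df$case_id)
    if (any(dup)) {
        warning("rejecting row(s) ", paste(which(dup) + 2L, collapse = ", "),
                " of ", basename(path), ": duplicate case_id",
                call. = FALSE)
        bad <- bad | dup
    }
    df[!bad, , drop = FALSE]
}

#' Write and read long-format Cq tables
#'
#' Long-format Cq tables have columns `sample_id`, `gene_id`, `role`,
#' `replicate`, `cq`; the calibrator run is identified by a reserved
#' sample id (default `"POS_CTRL"`).
#'
#' @param x a [CqRunSet-class] to write.
#' @param path file path; `.tsv`/`.txt` selects tab separation.
#' @param sep overrides the inferred separator.
#' @param calibrator sample id of the positive-control run.
#' @return `writeCqTable()` returns `path` invisibly; `readCqTable()` a
#'   validated [CqRunSet-class].
#' @export
writeCqTable <- function(x, path, sep = NULL) {
    stopifnot(is(x, "CqRunSet"))
    sep <- .sepFor(path, sep)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.CQ_SCHEMA_TAG, con)
    utils::write.table(cqData(x), con, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeCqTable
#' @export
readCqTable <- function(path, sep = NULL, calibrator = "POS_CTRL") {
    sep <- .sepFor(path, sep)
    first <- readLines(path, n = 1L)
    if (!identical(first, .CQ_SCHEMA_TAG))
        stop("not a Cq table (missing schema header '", .CQ_SCHEMA_TAG,
             "'): ", path, call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    CqRunSet(df, calibrator = calibrator)
}

## Marker calls in long format for one cohort's case table plus RU table.
.buildCallTable <- function(cases, ru, thresholds) {
    out <- list()
    for (g in c("ESR1", "PGR", "MKI67")) {
        mk <- ihcMarkerOf(g)
        col <- tolower(mk)
        for (m in c("ORI", "REV", "DIA")) {
            v <- cases[[paste0(col, "_", m)]]
            out[[paste(g, m)]] <- data.frame(
                case_id = cases$case_id, marker = mk, method = m,
                category = classifyIHCPercent(mk, v, thresholds),
                source_value = v, stringsAsFactors = FALSE)
        }
    }
    for (m in c("ORI", "REV")) {
        sc <- cases[[paste0("her2_ihc_", m)]]
        out[[paste("HER2", m)]] <- data.frame(
            case_id = cases$case_id, marker = "HER2", method = m,
            category = classifyHER2IHC(sc),
            source_value = NA_real_, stringsAsFactors = FALSE)
    }
    ru_by_gene <- split(ru, ru$gene_id)
    for (g in .TARGET_GENES) {
        rg <- ru_by_gene[[g]]
        rg <- rg[match(cases$case_id, rg$sample_id), , drop = FALSE]
        out[[paste(g, "RTqPCR")]] <- data.frame(
            case_id = cases$case_id, marker = ihcMarkerOf(g),
            method = "RTqPCR",
            category = classifyRU(g, rg$ru, thresholds),
            source_value = rg$ru, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.getCalls <- function(calls, marker, method) {
    sel <- calls[calls$marker == marker & calls$method == method, ]
    sel$category
}

#' Run the full method-comparison pipeline
#'
#' Orchestrates the end-to-end analysis on a synthetic cohort: relative
#' -units quantification of the Cq panels, categorical classification of
#' every method's measurements, HER2 reflex-FISH resolution, paired
#' -method agreement statistics, Ki67 zone breakdown, surrogate
#' subtyping and subtype redistribution. Deterministic given the
#' configuration seed.
#'
#' DIA produces no HER2 read; the DIA subtyping path borrows the
#' REV-resolved HER2 status. The RT-qPCR subtyping path uses the RU
#' categories throughout, mapping the ERBB2 Equivocal zone to
#' HER2-negative for subtype purposes (expression below the cutoff).
#'
#' @param config a [simConfig()] configuration.
#' @param thresholds registry from [markerThresholds()].
#' @param out_dir optional directory; when given, the result tables are
#'   written as CSV and the metrics as JSON.
#' @param ba_threshold Bland-Altman flagging threshold (percentage
#'   points).
#' @return list with elements `cohort`, `ru_table`, `call_table`,
#'   `her2_resolved`, `agreement`, `bland_altman`, `ki67_zones`,
#'   `subtypes`, `redistribution`, `metrics`.
#' @export
runPipeline <- function(config = simConfig(),
                        thresholds = markerThresholds(),
                        out_dir = NULL, ba_threshold = 10) {
    cohort <- generateCohort(config)
    cases <- caseTable(cohort)
    ru <- computeRU(cqRuns(cohort), raw_cutoffs = config$raw_cutoffs)
    calls <- .buildCallTable(cases, ru, thresholds)

    ## HER2 reflex resolution per IHC method
    fish_cat <- rep(NA_character_, nrow(cases))
    has_fish <- !is.na(cases$fish_ratio) & !is.na(cases$fish_copies)
    if (any(has_fish))
        fish_cat[has_fish] <- as.character(
            classifyFISH(cases$fish_ratio[has_fish],
                         cases$fish_copies[has_fish]))
    her2_res <- data.frame(
        case_id = cases$case_id,
        fish_category = fish_cat,
        ORI = resolveHER2(cases$her2_ihc_ORI, fish_cat),
        REV = resolveHER2(cases$her2_ihc_REV, fish_cat),
        stringsAsFactors = FALSE)

    ## continuous agreement per marker and method pair
    pairs <- expand.grid(marker = c("ER", "PR", "Ki67"),
                         pair = c("ORI-REV", "ORI-DIA"),
                         stringsAsFactors = FALSE)
    agree <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        mk <- pairs$marker[i]
        col <- tolower(mk)
        other <- sub("ORI-", "", pairs$pair[i])
        a <- cases[[paste0(col, "_ORI")]]
        b <- cases[[paste0(col, "_", other)]]
        cbind(data.frame(marker = mk, pair = pairs$pair[i]),
              agreementSummary(a, b, threshold = ba_threshold))
    }))
    ## IHC vs RT-qPCR correlation (percent vs RU, Table-4 style)
    ru_by_gene <- split(ru, ru$gene_id)
    qpcr_cor <- do.call(rbind, lapply(c("ESR1", "PGR", "MKI67"),
                                      function(g) {
        mk <- ihcMarkerOf(g)
        rg <- ru_by_gene[[g]]
        rg <- rg[match(cases$case_id, rg$sample_id), ]
        data.frame(marker = mk, pair = "ORI-RTqPCR",
                   pearson_r = pearsonR(
                       cases[[paste0(tolower(mk), "_ORI")]], rg$ru)$r)
    }))

    ## Bland-Altman per case, per marker, ORI vs REV and ORI vs DIA
    ba <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        mk <- pairs$marker[i]
        col <- tolower(mk)
        other <- sub("ORI-", "", pairs$pair[i])
        cbind(data.frame(marker = mk, pair = pairs$pair[i]),
              blandAltman(cases[[paste0(col, "_ORI")]],
                          cases[[paste0(col, "_", other)]],
                          threshold = ba_threshold,
                          case_ids = cases$case_id))
    }))

    ## Ki67 zone breakdown of categorical discordance (ORI category vs
    ## either re-assessment)
    k_ori <- .getCalls(calls, "Ki67", "ORI")
    k_rev <- .getCalls(calls, "Ki67", "REV")
    k_dia <- .getCalls(calls, "Ki67", "DIA")
    disc_any <- k_ori != k_rev | k_ori != k_dia
    zones <- ki67Zone(cases$ki67_ORI)
    ki67_zones <- rateByZone(zones, disc_any,
                             levels = c("Low", "Intermediate", "High"))

    ## subtyping per method
    st <- function(er, pr, her2, ki) as.character(
        assignSubtype(er, pr, her2, ki))
    subtypes <- data.frame(
        case_id = cases$case_id,
        ORI = st(.getCalls(calls, "ER", "ORI"), .getCalls(calls, "PR", "ORI"),
                 her2_res$ORI, k_ori),
        REV = st(.getCalls(calls, "ER", "REV"), .getCalls(calls, "PR", "REV"),
                 her2_res$REV, k_rev),
        DIA = st(.getCalls(calls, "ER", "DIA"), .getCalls(calls, "PR", "DIA"),
                 her2_res$REV, k_dia),
        RTqPCR = st(.getCalls(calls, "ER", "RTqPCR"),
                    .getCalls(calls, "PR", "RTqPCR"),
                    ifelse(.getCalls(calls, "HER2", "RTqPCR") == "Positive",
                           "Positive", "Negative"),
                    .getCalls(calls, "Ki67", "RTqPCR")),
        stringsAsFactors = FALSE)
    redist <- list(REV = redistribution(subtypes$ORI, subtypes$REV),
                   DIA = redistribution(subtypes$ORI, subtypes$DIA),
                   RTqPCR = redistribution(subtypes$ORI, subtypes$RTqPCR))

    disc <- list(
        ki67_cat_ORI_REV = discordanceRate(k_ori, k_rev),
        ki67_cat_ORI_DIA = discordanceRate(k_ori, k_dia),
        subtype_ORI_REV = discordanceRate(subtypes$ORI, subtypes$REV),
        subtype_ORI_RTqPCR = discordanceRate(subtypes$ORI, subtypes$RTqPCR))

    metrics <- list(
        package_version = as.character(utils::packageVersion("brcaConcord")),
        seed = config$seed,
        n_cases = config$n_cases,
        config_hash = rlang::hash(unclass(config)),
        discordance = lapply(disc, function(d)
            d[c("n_discordant", "n", "rate")]),
        ki67_zone_rates = stats::setNames(as.list(ki67_zones$rate),
                                          ki67_zones$zone),
        luminal_a_switch = lapply(redist, function(r) {
            sr <- r$switch_rates
            sr$rate[sr$subtype == "Luminal A-like"]
        }))

    result <- list(cohort = cohort, ru_table = ru, call_table = calls,
                   her2_resolved = her2_res,
                   agreement = rbind(
                       agree[, c("marker", "pair", "n", "median_delta",
                                 "median_abs_delta", "sd_abs_delta", "icc",
                                 "pearson_r", "n_over_threshold",
                                 "rate_over_threshold")]),
                   qpcr_correlation = qpcr_cor,
                   bland_altman = ba, ki67_zones = ki67_zones,
                   subtypes = subtypes, redistribution = redist,
                   metrics = metrics)

    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        w <- function(x, f) utils::write.csv(
            x, file.path(out_dir, f), row.names = FALSE)
        ru_out <- ru
        ru_out$ru <- round(ru_out$ru, 3)
        ru_out$ddcq <- round(ru_out$ddcq, 3)
        w(ru_out, "ru_table.csv")
        w(calls, "call_table.csv")
        w(her2_res, "her2_resolved.csv")
        w(result$agreement, "agreement.csv")
        w(qpcr_cor, "qpcr_correlation.csv")
        w(ba, "bland_altman.csv")
        w(ki67_zones, "ki67_zones.csv")
        w(subtypes, "subtypes.csv")
        w(as.data.frame(redist$REV$table), "redistribution_ORI_REV.csv")
        jsonlite::write_json(metrics,
                             file.path(out_dir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    result
}
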