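## Relative-units quantification from raw Cq replicates.
##
## RU = ddCq - raw_cutoff, where ddCq is doubly normalized on the log2
## scale: target vs combined reference genes, sample vs positive control.
## Sign convention: ddCq = (reference - target)_sample -
## (reference - target)_calibrator, so that HIGHER expression (lower target
## Cq) gives HIGHER ddCq and RU > 0 means expression above the marker
## cutoff. See the methods vignette for why the orientation is fixed this
## way.

#' Median Cq of a replicate set
#'
#' Computes the median quantification cycle over valid replicates.
#' Undetermined replicates (`NA`) and values beyond the detection limit
#' (`> max_cq`) are excluded before taking the median; a replicate set with
#' no valid value is a quantification failure and raises an error rather
#' than imputing.
#'
#' @param cq numeric vector of replicate Cq values (cycles).
#' @param max_cq detection limit in cycles; values above it are treated as
#'   undetected. Default 40.
#' @param sample_id,gene_id identifiers used in error messages.
#' @return median Cq in cycles (numeric scalar).
#' @examples
#' medianCq(c(24.8, 25.2, 31.0))
#' medianCq(c(26, NA, 27))   # invalid excluded -> 26.5
#' @export
medianCq <- function(cq, max_cq = 40, sample_id = "?", gene_id = "?") {
    valid <- cq[is.finite(cq) & cq <= max_cq]
    if (!length(valid))
        stop("quantification failure: no valid Cq replicate for sample '",
             sample_id, "', gene '", gene_id, "'", call. = FALSE)
    if (length(valid) < 2L)
        warning("single valid Cq replicate for sample '", sample_id,
                "', gene '", gene_id, "'", call. = FALSE)
    stats::median(valid)
}

#' Combined reference Cq
#'
#' Aggregates per-reference-gene median Cq values into the single
#' "combined reference" used for normalization. The aggregation rule is
#' configurable; the default is the arithmetic mean of the per-gene
#' medians.
#'
#' @param reference_medians numeric vector, one median Cq per reference
#'   gene.
#' @param method `"mean"` (default) or `"median"`.
#' @return combined reference Cq in cycles, with the aggregation method
#'   attached as attribute `"method"` for provenance.
#' @examples
#' combinedReference(c(26, 28))
#' @export
combinedReference <- function(reference_medians, method = c("mean", "median")) {
    method <- match.arg(method)
    if (!length(reference_medians))
        stop("no reference-gene medians supplied", call. = FALSE)
    out <- switch(method,
        mean = mean(reference_medians),
        median = stats::median(reference_medians))
    structure(out, method = method)
}

## Internal: median target Cq and combined reference from one sample's rows.
.runSummaryRows <- function(rows, sample_id, gene_id, ref_method,
                            max_cq = 40) {
    tgt <- rows[rows$gene_id == gene_id & rows$role == "target", , drop = FALSE]
    if (!nrow(tgt))
        stop("gene '", gene_id, "' absent from sample '", sample_id, "'",
             call. = FALSE)
    refs <- rows[rows$role == "reference", , drop = FALSE]
    if (!nrow(refs))
        stop("no reference-gene measurements in sample '", sample_id, "'",
             call. = FALSE)
    ref_meds <- vapply(split(refs$cq, refs$gene_id), medianCq, numeric(1),
                       max_cq = max_cq, sample_id = sample_id)
    list(median_target = medianCq(tgt$cq, max_cq = max_cq,
                                  sample_id = sample_id, gene_id = gene_id),
         combined_reference = as.numeric(
             combinedReference(ref_meds, method = ref_method)),
         reference_genes = paste(sort(names(ref_meds)), collapse = "+"))
}

.runSummary <- function(df, sample_id, gene_id, ref_method, max_cq = 40) {
    rows <- df[df$sample_id == sample_id, , drop = FALSE]
    .runSummaryRows(rows, sample_id, gene_id, ref_method, max_cq)
}

#' Delta-delta-Cq for one gene of one sample run
#'
#' Doubly normalized log2 expression: the target gene's median Cq is
#' normalized against the combined reference within the run, then against
#' the same contrast in the positive-control (calibrator) run. The sign is
#' oriented so that higher expression (lower target Cq) yields a higher
#' value: `ddCq = (ref - target)_sample - (ref - target)_calibrator`.
#'
#' @param runs a [CqRunSet-class].
#' @param sample_id sample to quantify.
#' @param gene_id one of [targetGenes()].
#' @param ref_method aggregation rule for [combinedReference()].
#' @return ddCq in log2 expression units (numeric scalar).
#' @examples
#' df <- expand.grid(sample_id = c("S1", "PC"),
#'                   gene_id = c("ESR1", "B2M"), replicate = 1L)
#' df$role <- ifelse(df$gene_id == "B2M", "reference", "target")
#' df$cq <- c(24, 25, 26, 26)  # S1 target 24, PC target 25, refs 26
#' deltaDeltaCq(CqRunSet(df, "PC"), "S1", "ESR1")  # 1: twofold higher
#' @export
deltaDeltaCq <- function(runs, sample_id, gene_id,
                         ref_method = c("mean", "median")) {
    stopifnot(is(runs, "CqRunSet"))
    ref_method <- match.arg(ref_method)
    if (!gene_id %in% .TARGET_GENES)
        stop("'", gene_id, "' is not a registered target gene", call. = FALSE)
    s <- .runSummary(runs@cq, sample_id, gene_id, ref_method)
    k <- .runSummary(runs@cq, calibratorId(runs), gene_id, ref_method)
    (s$combined_reference - s$median_target) -
        (k$combined_reference - k$median_target)
}

#' Center a delta-delta-Cq value on the marker cutoff
#'
#' Transforms ddCq to relative units (RU) by subtracting the
#' marker-specific raw cutoff, an instrument calibration constant on the
#' log2 scale. RU = 0 exactly when expression sits at the clinical decision
#' boundary; positive RU means expression above the cutoff.
#'
#' @param ddcq delta-delta-Cq (log2 units).
#' @param raw_cutoff marker-specific cutoff on the ddCq scale (log2 units).
#' @return relative units (log2 scale, centered).
#' @examples
#' toRU(1.0, 0.5)
#' @export
toRU <- function(ddcq, raw_cutoff) {
    if (is.null(raw_cutoff) || length(raw_cutoff) != 1L || is.na(raw_cutoff))
        stop("raw cutoff not configured", call. = FALSE)
    ddcq - raw_cutoff
}

#' Relative-units table for a whole run set
#'
#' Quantifies every target gene of every sample in a [CqRunSet-class]
#' against the positive-control run and centers the result on the
#' per-gene raw cutoffs, returning one row per sample and gene with full
#' provenance (median Cqs, combined references, reference-gene combination,
#' calibrator identity).
#'
#' @param runs a [CqRunSet-class].
#' @param raw_cutoffs named numeric vector of per-gene cutoffs on the ddCq
#'   scale; must cover every target gene present. Defaults to 0 for all
#'   four target genes (cutoffs are assay calibration constants supplied
#'   with the instrument configuration).
#' @param ref_method aggregation rule for [combinedReference()].
#' @return `data.frame` with columns `sample_id`, `gene_id`,
#'   `median_cq_target`, `combined_reference`, `median_cq_target_cal`,
#'   `combined_reference_cal`, `ddcq`, `raw_cutoff`, `ru`,
#'   `reference_genes`, `ref_method`, `calibrator`.
#' @seealso [deltaDeltaCq()], [toRU()]
#' @export
computeRU <- function(runs,
                      raw_cutoffs = c(ESR1 = 0, PGR = 0, ERBB2 = 0, MKI67 = 0),
                      ref_method = c("mean", "median")) {
    stopifnot(is(runs, "CqRunSet"))
    ref_method <- match.arg(ref_method)
    df <- runs@cq
    genes <- intersect(.TARGET_GENES, unique(df$gene_id))
    miss <- setdiff(genes, names(raw_cutoffs))
    if (length(miss))
        stop("raw cutoff not configured for gene(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    samples <- sampleIds(runs)
    cal_id <- calibratorId(runs)
    by_sample <- split(df, df$sample_id)
    cal <- lapply(genes, function(g)
        .runSummaryRows(by_sample[[cal_id]], cal_id, g, ref_method))
    names(cal) <- genes
    grid <- expand.grid(gene_id = genes, sample_id = samples,
                        stringsAsFactors = FALSE)[, 2:1]
    s <- Map(function(sid, g) .runSummaryRows(by_sample[[sid]], sid, g,
                                              ref_method),
             grid$sample_id, grid$gene_id)
    med_t <- vapply(s, `[[`, numeric(1), "median_target")
    comb  <- vapply(s, `[[`, numeric(1), "combined_reference")
    refs  <- vapply(s, `[[`, character(1), "reference_genes")
    med_c <- vapply(cal[grid$gene_id], `[[`, numeric(1), "median_target")
    comb_c <- vapply(cal[grid$gene_id], `[[`, numeric(1),
                     "combined_reference")
    ddcq <- (comb - med_t) - (comb_c - med_c)
    cuts <- unname(raw_cutoffs[grid$gene_id])
    data.frame(sample_id = grid$sample_id, gene_id = grid$gene_id,
               median_cq_target = med_t, combined_reference = comb,
               median_cq_target_cal = unname(med_c),
               combined_reference_cal = unname(comb_c),
               ddcq = ddcq, raw_cutoff = cuts, ru = ddcq - cuts,
               reference_genes = refs, ref_method = ref_method,
               calibrator = cal_id, stringsAsFactors = FALSE,
               row.names = NULL)
}
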