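## Categorical classification of continuous and ordinal biomarker
## measurements: RU breakpoints with the ERBB2 equivocal zone, IHC
## percentage breakpoints, HER2 ordinal scores, dual-probe FISH rules
## (2013 ASCO/CAP edition) and the reflex resolution combining them.
## All intervals are left-closed/right-open: a printed ">= x" breakpoint
## assigns x itself to the upper category.

.DEFAULT_THRESHOLDS <- list(
    ESR1 = list(
        ru  = list(breaks = c(0, 1.1),
                   labels = c("Negative", "Low Positive", "High Positive")),
        ihc = list(breaks = c(1, 50),
                   labels = c("Negative", "Low Positive", "High Positive"))),
    PGR = list(
        ru  = list(breaks = c(0, 0.5),
                   labels = c("Negative", "Low Positive", "High Positive")),
        ihc = list(breaks = c(1, 20),
                   labels = c("Negative", "Low Positive", "High Positive"))),
    ERBB2 = list(
        ru  = list(breaks = c(-0.7, 0),
                   labels = c("Negative", "Equivocal", "Positive")),
        ihc = list(ordinal = list("0" = "Negative", "1+" = "Negative",
                                  "2+" = "Equivocal", "3+" = "Positive"))),
    MKI67 = list(
        ru  = list(breaks = 0, labels = c("Low", "High")),
        ihc = list(breaks = 20, labels = c("Low", "High")))
)

#' Marker classification thresholds
#'
#' The registry of category breakpoints per marker gene, on both the
#' relative-units (RU) scale and the IHC-equivalent scale:
#' \itemize{
#'   \item ESR1/ER: Negative < 0 RU (< 1\%), Low Positive to 1.1 RU
#'     (to 50\%), High Positive at or above.
#'   \item PGR/PR: Negative < 0 RU (< 1\%), Low Positive to 0.5 RU
#'     (to 20\%), High Positive at or above.
#'   \item ERBB2/HER2: Negative < -0.7 RU, Equivocal in [-0.7, 0),
#'     Positive at or above 0; IHC ordinal 0/1+ Negative, 2+ Equivocal,
#'     3+ Positive.
#'   \item MKI67/Ki67: Low < 0 RU (< 20\%), High at or above.
#' }
#' Every breakpoint belongs to its upper category (left-closed intervals).
#'
#' @param path optional YAML file overriding the built-in registry (same
#'   structure as produced by [writeThresholds()]).
#' @return nested list keyed by gene id, each with `ru` and `ihc` entries
#'   carrying `breaks` and `labels` (or an `ordinal` map for HER2 IHC).
#' @seealso [classifyRU()], [classifyIHCPercent()], [writeThresholds()]
#' @export
markerThresholds <- function(path = NULL) {
    if (is.null(path))
        return(.DEFAULT_THRESHOLDS)
    thr <- yaml::read_yaml(path)
    for (g in names(thr)) {
        for (scale in names(thr[[g]])) {
            b <- thr[[g]][[scale]]$breaks
            if (!is.null(b) && is.unsorted(b, strictly = TRUE))
                stop("breakpoints for ", g, "/", scale,
                     " must be strictly increasing", call. = FALSE)
        }
    }
    thr
}

#' Write the threshold registry to YAML
#'
#' Serializes a threshold registry (by default the built-in one) to a
#' declarative YAML file that can be edited and passed back to
#' [markerThresholds()].
#'
#' @param path output file path.
#' @param thresholds registry to write.
#' @return `path`, invisibly.
#' @export
writeThresholds <- function(path, thresholds = markerThresholds()) {
    yaml::write_yaml(thresholds, path)
    invisible(path)
}

## Interval lookup honouring ">= x" semantics: breaks are the lower edges
## of the upper categories.
.cutLabel <- function(x, breaks, labels) {
    idx <- findInterval(x, breaks, left.open = FALSE) + 1L
    labels[idx]
}

#' Classify a relative-units value
#'
#' Maps an RU value to its marker category using left-closed intervals:
#' for ERBB2 an RU of exactly -0.7 is Equivocal and 0 is Positive; an RU
#' in [-0.7, 0) is never Negative (the equivocal rescue zone).
#'
#' @param gene_id one of [targetGenes()] (vectorized, recycled against
#'   `ru`).
#' @param ru numeric vector of relative-units values; must be finite.
#' @param thresholds registry from [markerThresholds()].
#' @return character vector of category labels.
#' @examples
#' classifyRU("ERBB2", c(-0.71, -0.7, -0.001, 0))
#' classifyRU("ESR1", 1.1)
#' @export
classifyRU <- function(gene_id, ru, thresholds = markerThresholds()) {
    n <- max(length(gene_id), length(ru))
    gene_id <- rep_len(gene_id, n)
    ru <- rep_len(ru, n)
    if (any(!is.finite(ru)))
        stop("RU values must be finite", call. = FALSE)
    vapply(seq_len(n), function(i) {
        thr <- thresholds[[gene_id[i]]]
        if (is.null(thr))
            stop("no thresholds registered for gene '", gene_id[i], "'",
                 call. = FALSE)
        .cutLabel(ru[i], thr$ru$breaks, thr$ru$labels)
    }, character(1))
}

#' Classify an IHC percentage score
#'
#' Maps a percentage of positively stained tumor nuclei to the marker's
#' IHC-equivalent category. Percentages are taken as continuous (digital
#' image analysis yields non-integers) and are not rounded before the
#' thresholds are applied.
#'
#' @param marker "ER", "PR" or "Ki67" (vectorized, recycled).
#' @param percent numeric vector in [0, 100].
#' @param thresholds registry from [markerThresholds()].
#' @return character vector of category labels.
#' @examples
#' classifyIHCPercent("ER", c(0.5, 1, 49.9, 50))
#' classifyIHCPercent("Ki67", c(19.9, 20))
#' @export
classifyIHCPercent <- function(marker, percent,
                               thresholds = markerThresholds()) {
    n <- max(length(marker), length(percent))
    marker <- rep_len(marker, n)
    percent <- rep_len(percent, n)
    if (any(!is.finite(percent) | percent < 0 | percent > 100))
        stop("IHC percentages must lie in [0, 100]", call. = FALSE)
    gene <- names(.IHC_MARKERS)[match(marker, .IHC_MARKERS)]
    if (anyNA(gene) || any(gene == "ERBB2"))
        stop("marker must be one of ER, PR, Ki67", call. = FALSE)
    vapply(seq_len(n), function(i) {
        thr <- thresholds[[gene[i]]]$ihc
        .cutLabel(percent[i], thr$breaks, thr$labels)
    }, character(1))
}

#' Classify a HER2 IHC ordinal score
#'
#' @param score character vector with levels "0", "1+", "2+", "3+".
#' @return "Negative" (0/1+), "Equivocal" (2+) or "Positive" (3+).
#' @examples
#' classifyHER2IHC(c("0", "1+", "2+", "3+"))
#' @export
classifyHER2IHC <- function(score) {
    map <- .DEFAULT_THRESHOLDS$ERBB2$ihc$ordinal
    bad <- setdiff(unique(score), names(map))
    if (length(bad))
        stop("unknown HER2 IHC score(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    unlist(map[score], use.names = FALSE)
}

#' Classify a dual-probe HER2 FISH result
#'
#' Applies the 2013 ASCO/CAP dual-probe rules: amplified (Positive) when
#' the HER2/CEP17 ratio is at least 2.0, or when the ratio is below 2.0
#' but the mean HER2 copy number reaches 6.0 signals/cell; Equivocal for
#' ratio below 2.0 with mean copies in [4.0, 6.0); Negative otherwise.
#' The guideline edition is recorded in the result so later editions can
#' be slotted in.
#'
#' @param ratio HER2/CEP17 signal ratio (vectorized).
#' @param copies mean HER2 signals per cell.
#' @return character vector "Positive"/"Equivocal"/"Negative" with
#'   attribute `guideline = "ASCO/CAP 2013"`.
#' @examples
#' classifyFISH(c(2.0, 1.5, 1.2), c(3.0, 4.0, 3.9))
#' @export
classifyFISH <- function(ratio, copies) {
    n <- max(length(ratio), length(copies))
    ratio <- rep_len(ratio, n)
    copies <- rep_len(copies, n)
    if (any(is.na(ratio) | is.na(copies)))
        stop("FISH ratio and mean copy number are both required",
             call. = FALSE)
    if (any(ratio <= 0) || any(copies < 0))
        stop("FISH ratio must be > 0 and copies >= 0", call. = FALSE)
    out <- ifelse(ratio >= 2 | copies >= 6, "Positive",
           ifelse(copies >= 4, "Equivocal", "Negative"))
    structure(out, guideline = "ASCO/CAP 2013")
}

#' Resolve HER2 status from IHC with reflex FISH
#'
#' Implements the reflex algorithm: IHC 3+ is Positive and 0/1+ Negative
#' outright; IHC 2+ (equivocal) defers to the FISH category when one is
#' available and is otherwise reported as "Equivocal-unresolved" — a
#' flagged state, not an error.
#'
#' @param ihc_score HER2 IHC ordinal scores ("0", "1+", "2+", "3+").
#' @param fish_category FISH categories from [classifyFISH()], or `NA`
#'   where no FISH was run.
#' @return character vector of resolved statuses.
#' @examples
#' resolveHER2(c("3+", "2+", "2+", "0"), c(NA, "Positive", NA, NA))
#' @export
resolveHER2 <- function(ihc_score, fish_category = NA_character_) {
    n <- max(length(ihc_score), length(fish_category))
    ihc_score <- rep_len(ihc_score, n)
    fish_category <- rep_len(as.character(fish_category), n)
    ihc <- classifyHER2IHC(ihc_score)
    out <- ihc
    eq <- ihc == "Equivocal"
    out[eq & !is.na(fish_category)] <- fish_category[eq & !is.na(fish_category)]
    out[eq & is.na(fish_category)] <- "Equivocal-unresolved"
    out
}

#' Tripartite Ki67 zoning
#'
#' Splits the Ki67 scale into an unequivocally Low zone (below 9\%), an
#' Intermediate zone (9\% to 30\%, both ends inclusive) where scoring
#' disagreement concentrates, and an unequivocally High zone (above
#' 30\%).
#'
#' @param percent numeric vector in [0, 100].
#' @param lower,upper zone boundaries (default 9 and 30).
#' @return character vector "Low"/"Intermediate"/"High".
#' @examples
#' ki67Zone(c(5.5, 9, 15, 30, 33.5))
#' @export
ki67Zone <- function(percent, lower = 9, upper = 30) {
    if (any(!is.finite(percent) | percent < 0 | percent > 100))
        stop("Ki67 percentages must lie in [0, 100]", call. = FALSE)
    ifelse(percent < lower, "Low",
           ifelse(percent <= upper, "Intermediate", "High"))
}
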