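## St. Gallen surrogate molecular subtyping from ER, PR, HER2 and Ki67
## calls, and subtype redistribution between assessment methods.

.SUBTYPE_LEVELS <- c("Luminal A-like", "Luminal B-like (HER2-)",
                     "Luminal B-like (HER2+)", "HER2-positive (non-luminal)",
                     "Triple-negative")

#' Surrogate subtype level set
#'
#' @return character vector of the five surrogate subtype labels in
#'   canonical order.
#' @export
subtypeLevels <- function() .SUBTYPE_LEVELS

#' Assign St. Gallen surrogate molecular subtypes
#'
#' Derives the clinicopathological surrogate subtype from resolved marker
#' calls (2013 expert-panel definitions):
#' \itemize{
#'   \item HER2 Positive with ER (or PR) positivity: Luminal B-like
#'     (HER2+); HER2 Positive without hormone-receptor expression:
#'     HER2-positive (non-luminal).
#'   \item HER2 Negative, ER positive: Luminal A-like when Ki67 is Low
#'     and PR is High Positive (at least the 20\% / 0.5 RU equivalent),
#'     otherwise Luminal B-like (HER2-).
#'   \item ER, PR and HER2 all Negative: Triple-negative.
#' }
#' ER-negative but PR-positive tumors are treated as hormone-receptor
#' positive (luminal B-like branch of the matching HER2 arm) and flagged,
#' since the surrogate definitions do not address them explicitly.
#'
#' HER2 must be resolved ("Positive"/"Negative"): an
#' "Equivocal"/"Equivocal-unresolved" status is an error instructing the
#' caller to run [resolveHER2()] first.
#'
#' @param er,pr categories "Negative"/"Low Positive"/"High Positive"
#'   (vectorized).
#' @param her2 resolved statuses "Positive"/"Negative".
#' @param ki67 categories "Low"/"High".
#' @param require_pr_high if `TRUE` (default), Luminal A-like requires PR
#'   High Positive; if `FALSE` the PR criterion is dropped and Ki67 alone
#'   separates Luminal A-like from Luminal B-like (HER2-).
#' @return character vector of subtype labels with logical attribute
#'   `"flagged"` marking ER-negative/PR-positive assignments.
#' @examples
#' assignSubtype("High Positive", "High Positive", "Negative", "Low")
#' assignSubtype("Negative", "Negative", "Negative", "High")
#' @export
assignSubtype <- function(er, pr, her2, ki67, require_pr_high = TRUE) {
    n <- max(length(er), length(pr), length(her2), length(ki67))
    er <- rep_len(er, n); pr <- rep_len(pr, n)
    her2 <- rep_len(her2, n); ki67 <- rep_len(ki67, n)
    if (any(!her2 %in% c("Positive", "Negative")))
        stop("HER2 status must be resolved to Positive/Negative; ",
             "run resolveHER2() first", call. = FALSE)
    pos_labels <- c("Low Positive", "High Positive")
    if (any(!er %in% c("Negative", pos_labels)) ||
        any(!pr %in% c("Negative", pos_labels)))
        stop("ER/PR categories must be Negative/Low Positive/High Positive",
             call. = FALSE)
    if (any(!ki67 %in% c("Low", "High")))
        stop("Ki67 category must be Low or High", call. = FALSE)
    er_pos <- er != "Negative"
    pr_pos <- pr != "Negative"
    hr_pos <- er_pos | pr_pos
    pr_high <- pr == "High Positive"
    her2_pos <- her2 == "Positive"
    lum_a <- !her2_pos & er_pos & ki67 == "Low" &
        (if (require_pr_high) pr_high else TRUE)
    out <- character(n)
    out[her2_pos & hr_pos] <- "Luminal B-like (HER2+)"
    out[her2_pos & !hr_pos] <- "HER2-positive (non-luminal)"
    out[!her2_pos & hr_pos] <- "Luminal B-like (HER2-)"
    out[lum_a] <- "Luminal A-like"
    out[!her2_pos & !hr_pos] <- "Triple-negative"
    structure(out, flagged = !er_pos & pr_pos)
}

#' Subtype redistribution between two methods
#'
#' Cross-tabulates subtype assignments from a reference method against an
#' alternative method and reports, per subtype, the percentage of cases
#' leaving it: `100 * (cases leaving S) / (cases originally S)`.
#'
#' @param calls_ref,calls_alt aligned subtype vectors (reference first).
#' @return list with `table` (reference in rows, alternative in columns)
#'   and `switch_rates` (`data.frame` with `subtype`, `n_ref`,
#'   `n_switched`, `rate` rounded half-up to one decimal, `rate_raw`;
#'   `NA` rate for subtypes absent from the reference).
#' @examples
#' redistribution(rep("Luminal A-like", 38),
#'                rep(c("Luminal A-like", "Luminal B-like (HER2-)"),
#'                    c(29, 9)))
#' @export
redistribution <- function(calls_ref, calls_alt) {
    .checkPair(calls_ref, calls_alt, 1L)
    tab <- crossTab(calls_ref, calls_alt, levels = .SUBTYPE_LEVELS)
    n_ref <- rowSums(tab)
    n_stay <- diag(tab)
    n_switch <- n_ref - n_stay
    raw <- ifelse(n_ref > 0, 100 * n_switch / n_ref, NA_real_)
    list(table = tab,
         switch_rates = data.frame(
             subtype = .SUBTYPE_LEVELS,
             n_ref = as.integer(n_ref),
             n_switched = as.integer(n_switch),
             rate = roundHalfUp(raw, 1),
             rate_raw = raw,
             row.names = NULL))
}
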