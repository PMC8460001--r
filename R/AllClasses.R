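## Marker-gene registry: the four MammaTyper-style target transcripts and the
## IHC marker names they stand for. Reference (housekeeping) genes are any
## other gene id declared with role "reference" in a Cq table.
.TARGET_GENES <- c("ESR1", "PGR", "ERBB2", "MKI67")
.IHC_MARKERS  <- c(ESR1 = "ER", PGR = "PR", ERBB2 = "HER2", MKI67 = "Ki67")
.METHODS      <- c("ORI", "REV", "DIA", "RTqPCR")

#' Target marker genes
#'
#' The four target transcripts quantified by the RT-qPCR panel and their
#' immunohistochemistry marker equivalents.
#'
#' @return `targetGenes()` returns the character vector of target gene ids;
#'   `ihcMarkerOf()` maps gene ids to IHC marker names ("ER", "PR", "HER2",
#'   "Ki67").
#' @param gene_id character vector of target gene ids.
#' @examples
#' targetGenes()
#' ihcMarkerOf("ESR1")
#' @export
targetGenes <- function() .TARGET_GENES

#' @rdname targetGenes
#' @export
ihcMarkerOf <- function(gene_id) {
    bad <- setdiff(gene_id, .TARGET_GENES)
    if (length(bad))
        stop("unknown target gene(s): ", paste(bad, collapse = ", "))
    unname(.IHC_MARKERS[gene_id])
}

#' CqRunSet: raw quantification-cycle replicate data
#'
#' An S4 container for long-format Cq replicate measurements across samples,
#' target genes and reference (housekeeping) genes, together with the
#' identity of the positive-control (calibrator) run used for delta-delta-Cq
#' normalization.
#'
#' The `cq` slot is a long-format `data.frame` with columns `sample_id`,
#' `gene_id`, `role` ("target" or "reference"), `replicate` and `cq`.
#' Undetermined replicates are stored as `NA`; Cq values above the
#' detection limit (40 cycles by convention) are retained as recorded and
#' excluded at quantification time.
#'
#' @slot cq long-format `data.frame` of replicate Cq values.
#' @slot calibrator `character(1)`, the `sample_id` of the positive-control
#'   run.
#' @name CqRunSet-class
#' @aliases CqRunSet-class
#' @exportClass CqRunSet
setClass("CqRunSet",
    representation(cq = "data.frame", calibrator = "character"))

setValidity("CqRunSet", function(object) {
    need <- c("sample_id", "gene_id", "role", "replicate", "cq")
    df <- object@cq
    miss <- setdiff(need, names(df))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (!all(df$role %in% c("target", "reference")))
        return("role must be 'target' or 'reference'")
    if (any(df$gene_id %in% .TARGET_GENES & df$role != "target"))
        return("target gene ids must carry role 'target'")
    if (any(!(df$gene_id %in% .TARGET_GENES) & df$role == "target"))
        return("role 'target' is reserved for the registered target genes")
    ok <- is.na(df$cq) | df$cq > 0
    if (!all(ok))
        return("finite Cq values must be positive")
    if (length(object@calibrator) != 1L || is.na(object@calibrator))
        return("calibrator must be a single sample_id")
    if (!object@calibrator %in% df$sample_id)
        return(paste0("calibrator '", object@calibrator,
                      "' not present in the Cq table"))
    TRUE
})

#' Construct a CqRunSet
#'
#' @param cq long-format `data.frame` with columns `sample_id`, `gene_id`,
#'   `role`, `replicate`, `cq`.
#' @param calibrator `sample_id` of the positive-control run.
#' @return a validated [CqRunSet-class] object.
#' @examples
#' df <- data.frame(sample_id = "S1", gene_id = c("ESR1", "B2M"),
#'                  role = c("target", "reference"), replicate = 1L,
#'                  cq = c(25, 18))
#' cal <- transform(df, sample_id = "PC")
#' CqRunSet(rbind(df, cal), calibrator = "PC")
#' @export
CqRunSet <- function(cq, calibrator) {
    cq <- as.data.frame(cq)
    cq$cq <- as.numeric(cq$cq)
    cq$replicate <- as.integer(cq$replicate)
    new("CqRunSet", cq = cq, calibrator = as.character(calibrator))
}

#' @describeIn CqRunSet-class long-format replicate table.
#' @param x,object a `CqRunSet`.
#' @export
cqData <- function(x) x@cq

#' @describeIn CqRunSet-class sample id of the positive-control run.
#' @export
calibratorId <- function(x) x@calibrator

#' @describeIn CqRunSet-class sample ids excluding the calibrator.
#' @export
sampleIds <- function(x) setdiff(unique(x@cq$sample_id), x@calibrator)

#' @describeIn CqRunSet-class reference gene ids present in the table.
#' @export
referenceGenes <- function(x) unique(x@cq$gene_id[x@cq$role == "reference"])

setMethod("show", "CqRunSet", function(object) {
    cat("CqRunSet with", length(sampleIds(object)), "sample run(s)\n")
    cat("  target genes   :",
        paste(intersect(.TARGET_GENES, unique(object@cq$gene_id)),
              collapse = ", "), "\n")
    cat("  reference genes:", paste(referenceGenes(object), collapse = ", "),
        "\n")
    cat("  calibrator     :", object@calibrator, "\n")
})

#' SyntheticCohort: a simulated paired multi-method cohort
#'
#' Holds one simulated cohort: the per-case table (latent truth, the three
#' IHC reads, HER2 ordinal scores, FISH inputs and generator truth labels),
#' the matching [CqRunSet-class] with the positive-control run, and the
#' generating configuration.
#'
#' @slot cases per-case `data.frame` (see [generateCohort()]).
#' @slot cqRuns a [CqRunSet-class] linked to the latent expression values.
#' @slot config the [simConfig()] list that produced the cohort.
#' @name SyntheticCohort-class
#' @aliases SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
    representation(cases = "data.frame", cqRuns = "CqRunSet",
                   config = "list"))

#' @describeIn SyntheticCohort-class per-case table.
#' @param x,object a `SyntheticCohort`.
#' @export
caseTable <- function(x) x@cases

#' @describeIn SyntheticCohort-class the cohort's Cq replicate data.
#' @export
cqRuns <- function(x) x@cqRuns

#' @describeIn SyntheticCohort-class the generating configuration.
#' @export
cohortConfig <- function(x) x@config

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort with", nrow(object@cases), "cases\n")
    cat("  seed:", object@config$seed, "\n")
    tl <- table(object@cases$truth_subtype)
    cat("  truth subtypes:\n")
    for (nm in names(tl)) cat(sprintf("    %-28s %d\n", nm, tl[[nm]]))
})
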