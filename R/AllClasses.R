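## Central S4 containers: compound library, assembled method set, and the
## feature-table experiment used by the statistics pipeline.

#' Canonical column set of a compound library
#'
#' Order is fixed; the on-disk TSV uses exactly these columns, with absent
#' values encoded as empty fields and pKa lists ";"-joined.
#' @keywords internal
.LIBRARY_COLUMNS <- c("kegg_id", "pubchem_sid", "pubchem_cid", "chembl_id",
                      "name", "smiles", "formula", "mw", "has_stereo",
                      "pka_acidic", "pka_basic")

#' Filter-chain stage names tracked by [libraryStats()]
#' @keywords internal
.LIBRARY_STAGES <- c("total", "with_sid", "with_cid", "with_chembl",
                     "with_pka")

#' CompoundLibrary: resolved metabolite records plus filter-chain statistics
#'
#' Holds one row per KEGG compound with the identifiers resolved along the
#' KEGG to PubChem SID to neutral-form CID/SMILES to ChEMBL-pKa chain, plus
#' the count of records surviving each stage of that chain. pKa values are
#' per functional group (one value per acidic or basic group), not
#' whole-molecule constants.
#'
#' @slot records data.frame with the canonical column set (see
#'   [writeLibrary()] for the on-disk contract): `kegg_id`, `pubchem_sid`,
#'   `pubchem_cid`, `chembl_id`, `name`, `smiles`, `formula` (character,
#'   `NA` when absent), `mw` (numeric, g/mol), `has_stereo` (logical),
#'   `pka_acidic`, `pka_basic` (";"-joined numeric strings, `NA` when no
#'   group of that kind).
#' @slot stats named integer vector of survivors at each chain stage
#'   (total, with_sid, with_cid, with_chembl, with_pka); non-increasing.
#'
#' @seealso [buildLibrary()], [readLibrary()], [organismMetabolome()]
#' @exportClass CompoundLibrary
setClass("CompoundLibrary",
         representation(records = "data.frame", stats = "integer"))

setValidity("CompoundLibrary", function(object) {
    rec <- object@records
    msgs <- character()
    if (!identical(colnames(rec), .LIBRARY_COLUMNS))
        msgs <- c(msgs, "records must have the canonical library columns")
    if (anyDuplicated(rec$kegg_id))
        msgs <- c(msgs, "kegg_id must be unique within a library")
    if (nrow(rec) && any(!is.na(rec$mw) & rec$mw <= 0))
        msgs <- c(msgs, "mw must be > 0 when present")
    haspka <- !is.na(rec$pka_acidic) | !is.na(rec$pka_basic)
    if (any(haspka & is.na(rec$chembl_id)))
        msgs <- c(msgs, "pKa values require a ChEMBL identifier")
    if (!identical(names(object@stats), .LIBRARY_STAGES))
        msgs <- c(msgs, "stats must cover the five chain stages")
    else if (is.unsorted(rev(object@stats)))
        msgs <- c(msgs, "filter-chain counts must be non-increasing")
    if (length(msgs)) msgs else TRUE
})

#' MrmMethodSet: selected transitions distributed into method packages
#'
#' The end product of method assembly: one selected transition per retained
#' metabolite (with origin, final polarity and convolution flag) and the
#' balanced distribution of those transitions into single-polarity method
#' packages of at most `max_per_package` transitions. One package corresponds
#' to one 1-minute flow-injection analysis, so the per-sample analysis
#' time in minutes equals the package count.
#'
#' @slot selection data.frame, one row per retained metabolite: `kegg_id`,
#'   `name`, `mode`, `q1`, `q3`, `ce`, `dp`, `ep`, `cxp`, `dwell`, `origin`,
#'   `intensity_rank`, `convolved`.
#' @slot packages list of data.frame, each a subset of `selection` rows with
#'   attributes `mode` and `index`.
#' @slot config list, the [builderConfig()] used for assembly.
#' @seealso [selectTransitions()], [packageMethods()], [formatMethodTables()]
#' @exportClass MrmMethodSet
setClass("MrmMethodSet",
         representation(selection = "data.frame", packages = "list",
                        config = "list"))

setValidity("MrmMethodSet", function(object) {
    msgs <- character()
    sel <- object@selection
    if (length(object@packages)) {
        sizes <- vapply(object@packages, nrow, integer(1))
        maxp <- object@config$max_per_package
        if (!is.null(maxp) && any(sizes > maxp))
            msgs <- c(msgs, "package exceeds max_per_package")
        ids <- unlist(lapply(object@packages, function(p) p$kegg_id))
        if (anyDuplicated(ids))
            msgs <- c(msgs, "a metabolite appears in more than one package")
        if (nrow(sel) && !setequal(ids, sel$kegg_id))
            msgs <- c(msgs, "packages must partition the selection")
        modes <- vapply(object@packages, function(p) {
            m <- unique(p$mode); if (length(m) == 1L) m else NA_character_
        }, character(1))
        if (anyNA(modes))
            msgs <- c(msgs, "each package must be single-polarity")
        for (m in unique(modes)) {
            sz <- sizes[modes == m]
            if (length(sz) && diff(range(sz)) > 1L)
                msgs <- c(msgs, "package sizes within a mode must differ by at most 1")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' MrmExperiment: injections-by-metabolite peak areas with S/N
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with assays `area` and `sn` (rows = metabolites, columns = injections) and
#' colData columns `sample_id`, `injection_order`, `type` (one of blank, qc,
#' sample) and `class` (sample class label, `NA` for blanks/QCs). This is the
#' container the statistics pipeline ([filterSn()] through
#' [selectVariables()]) operates on.
#'
#' @seealso [MrmExperiment()], [readFeatureTable()]
#' @exportClass MrmExperiment
setClass("MrmExperiment", contains = "SummarizedExperiment")

setValidity("MrmExperiment", function(object) {
    msgs <- character()
    if (!all(c("area", "sn") %in% assayNames(object)))
        msgs <- c(msgs, "assays 'area' and 'sn' are required")
    cd <- colData(object)
    need <- c("sample_id", "injection_order", "type", "class")
    if (!all(need %in% colnames(cd)))
        msgs <- c(msgs, paste("colData must provide",
                              paste(need, collapse = ", ")))
    else {
        if (is.unsorted(cd$injection_order, strictly = TRUE))
            msgs <- c(msgs, "injection_order must be strictly increasing")
        if (!all(cd$type %in% c("blank", "qc", "sample")))
            msgs <- c(msgs, "type must be blank, qc or sample")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct an MrmExperiment
#'
#' @param area numeric matrix, metabolites x injections, peak areas
#'   (arbitrary units); `NA` marks missing signals.
#' @param sn numeric matrix of the same shape, signal-to-noise ratios.
#' @param injection_order integer vector, one per column, strictly
#'   increasing.
#' @param type character vector per column: "blank", "qc" or "sample".
#' @param class character vector per column, sample class labels (`NA` for
#'   non-sample injections).
#' @param sample_id character vector per column; defaults to column names.
#' @return An [MrmExperiment-class] object.
#' @examples
#' area <- matrix(rlnorm(20), 4, 5,
#'                dimnames = list(paste0("C0000", 1:4), paste0("inj", 1:5)))
#' sn <- matrix(50, 4, 5)
#' mx <- MrmExperiment(area, sn, injection_order = 1:5,
#'                     type = c("blank", "qc", "sample", "sample", "qc"),
#'                     class = c(NA, NA, "A", "B", NA))
#' mx
#' @export
MrmExperiment <- function(area, sn, injection_order, type, class,
                          sample_id = colnames(area)) {
    stopifnot(is.matrix(area), identical(dim(area), dim(sn)))
    if (is.null(sample_id))
        sample_id <- paste0("S", seq_len(ncol(area)))
    cd <- DataFrame(sample_id = as.character(sample_id),
                    injection_order = as.integer(injection_order),
                    type = as.character(type),
                    class = as.character(class))
    se <- SummarizedExperiment(assays = list(area = area, sn = sn),
                               colData = cd)
    new("MrmExperiment", se)
}

#' @describeIn MrmExperiment-class number of compound records
#' @param x a `CompoundLibrary`
#' @aliases length,CompoundLibrary-method
#' @export
setMethod("length", "CompoundLibrary", function(x) nrow(x@records))

setMethod("show", "CompoundLibrary", function(object) {
    st <- object@stats
    cat("CompoundLibrary with", nrow(object@records), "records\n")
    cat("  chain: total", st["total"], "| SID", st["with_sid"],
        "| CID", st["with_cid"], "| ChEMBL", st["with_chembl"],
        "| pKa", st["with_pka"], "\n")
})

setMethod("show", "MrmMethodSet", function(object) {
    sizes <- vapply(object@packages, nrow, integer(1))
    modes <- vapply(object@packages,
                    function(p) as.character(attr(p, "mode")), character(1))
    cat("MrmMethodSet:", nrow(object@selection), "metabolites in",
        length(object@packages), "packages",
        sprintf("(%d positive, %d negative);", sum(modes == "positive"),
                sum(modes == "negative")),
        "analysis time", length(object@packages), "min/sample\n")
    if (length(sizes))
        cat("  package sizes:", paste(sizes, collapse = ", "), "\n")
    nconv <- sum(object@selection$convolved)
    cat("  convolved selections:", nconv, "\n")
})

#' Accessors for library, method-set and experiment objects
#'
#' `libraryRecords()` returns the record table of a [CompoundLibrary-class];
#' `libraryStats()` its filter-chain survivor counts; `keggIds()` its
#' compound identifiers. `selectedTransitions()` and `methodPackages()`
#' return the per-metabolite selection and the package list of an
#' [MrmMethodSet-class]. `injectionOrder()`, `sampleType()` and
#' `sampleClass()` read injection metadata from an [MrmExperiment-class].
#'
#' @param x the object
#' @return see details above
#' @name accessors
NULL

#' @rdname accessors
#' @export
libraryRecords <- function(x) {
    stopifnot(is(x, "CompoundLibrary"))
    x@records
}

#' @rdname accessors
#' @export
libraryStats <- function(x) {
    stopifnot(is(x, "CompoundLibrary"))
    x@stats
}

#' @rdname accessors
#' @export
keggIds <- function(x) {
    stopifnot(is(x, "CompoundLibrary"))
    x@records$kegg_id
}

#' @rdname accessors
#' @export
selectedTransitions <- function(x) {
    stopifnot(is(x, "MrmMethodSet"))
    x@selection
}

#' @rdname accessors
#' @export
methodPackages <- function(x) {
    stopifnot(is(x, "MrmMethodSet"))
    x@packages
}

#' @rdname accessors
#' @export
injectionOrder <- function(x) colData(x)$injection_order

#' @rdname accessors
#' @export
sampleType <- function(x) colData(x)$type

#' @rdname accessors
#' @export
sampleClass <- function(x) colData(x)$class
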