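## Identifier-chain resolution (KEGG -> PubChem SID -> neutral-form CID /
## SMILES -> ChEMBL -> per-group pKa) and library persistence.

.input_error <- function(msg, call. = FALSE) {
    stop(structure(class = c("fiamrm_input_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

.transport_error <- function(msg) {
    stop(structure(class = c("fiamrm_transport_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

#' Signal a retryable transport failure from a fetcher
#'
#' Fetcher implementations call this (or signal a condition inheriting from
#' `fiamrm_transport_error`) for network/transport failures, keeping them
#' distinct from an identifier that genuinely has no link ("absent", encoded
#' as `NA`).
#' @param msg error message
#' @export
transportError <- function(msg) .transport_error(msg)

#' Per-group pKa set
#'
#' Predicted acid dissociation constants of the individual acidic and basic
#' functional groups of a molecule (log10 units). These are per-group
#' constants, one per ionizable group, not whole-molecule values; at least
#' one of the two lists must be non-empty.
#'
#' @param acidic numeric vector of acidic-group pKa values (may be empty)
#' @param basic numeric vector of basic-group pKa values (may be empty)
#' @return list of class `PkaSet` with elements `acidic` and `basic`
#' @examples
#' pkaSet(acidic = c(2.2, 9.1), basic = 9.0)  # amino-acid-like
#' @export
pkaSet <- function(acidic = numeric(), basic = numeric()) {
    acidic <- as.numeric(acidic); basic <- as.numeric(basic)
    if (length(acidic) + length(basic) == 0L)
        .input_error("a PkaSet needs at least one acidic or basic group")
    if (!all(is.finite(acidic)) || !all(is.finite(basic)))
        .input_error("pKa values must be finite")
    structure(list(acidic = acidic, basic = basic), class = "PkaSet")
}

.parse_pka_field <- function(x) {
    if (is.na(x) || !nzchar(x)) return(numeric())
    as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

.join_pka_field <- function(v) {
    if (!length(v)) NA_character_ else paste(as.character(v), collapse = ";")
}

#' Extract the PkaSet of a library record
#'
#' @param record one-row data.frame in canonical library form (or a row of
#'   [libraryRecords()])
#' @return a [pkaSet()] or `NULL` when the record carries no pKa values
#' @export
recordPka <- function(record) {
    a <- .parse_pka_field(record$pka_acidic[1])
    b <- .parse_pka_field(record$pka_basic[1])
    if (!length(a) && !length(b)) return(NULL)
    pkaSet(a, b)
}

.has_stereo <- function(smiles) {
    !is.na(smiles) & grepl("[@/\\\\]", smiles)
}

.empty_record <- function() {
    data.frame(kegg_id = character(), pubchem_sid = character(),
               pubchem_cid = character(), chembl_id = character(),
               name = character(), smiles = character(),
               formula = character(), mw = numeric(),
               has_stereo = logical(), pka_acidic = character(),
               pka_basic = character(), stringsAsFactors = FALSE)
}

#' Build a fetcher from a local identifier table
#'
#' The identifier-resolution contract is a list of five functions answering
#' SID-for-KEGG, CID-for-SID, structure-for-CID, ChEMBL-for-CID and
#' pKa-for-ChEMBL queries; each may answer "absent" (`NA`/`NULL`). All
#' network use goes through this contract, so tests and offline runs use
#' table-backed fetchers such as this one.
#'
#' @param table data.frame with columns `kegg_id`, `pubchem_sid`,
#'   `pubchem_cid`, `chembl_id`, `name`, `smiles`, `formula`, `mw`,
#'   `pka_acidic`, `pka_basic` (the last two ";"-joined; empty/NA = absent).
#'   Rows are keyed by `kegg_id`; links below the first absent field are
#'   never consulted.
#' @return fetcher list with elements `sid_for_kegg`, `cid_for_sid`,
#'   `structure_for_cid`, `chembl_for_cid`, `pka_for_chembl`
#' @seealso [resolveChain()]
#' @export
tableFetcher <- function(table) {
    row_for <- function(col, key) {
        i <- which(!is.na(table[[col]]) & table[[col]] == key)
        if (length(i)) table[i[1], , drop = FALSE] else NULL
    }
    na_if_empty <- function(x)
        if (is.null(x) || is.na(x) || !nzchar(x)) NA_character_ else x
    list(
        sid_for_kegg = function(kegg_id) {
            r <- row_for("kegg_id", kegg_id)
            if (is.null(r)) NA_character_ else na_if_empty(r$pubchem_sid)
        },
        cid_for_sid = function(sid) {
            r <- row_for("pubchem_sid", sid)
            if (is.null(r)) NA_character_ else na_if_empty(r$pubchem_cid)
        },
        structure_for_cid = function(cid) {
            r <- row_for("pubchem_cid", cid)
            if (is.null(r)) return(NULL)
            list(smiles = na_if_empty(r$smiles),
                 formula = na_if_empty(r$formula),
                 mw = if (is.na(r$mw)) NA_real_ else as.numeric(r$mw),
                 name = na_if_empty(r$name))
        },
        chembl_for_cid = function(cid) {
            r <- row_for("pubchem_cid", cid)
            if (is.null(r)) NA_character_ else na_if_empty(r$chembl_id)
        },
        pka_for_chembl = function(chembl_id) {
            r <- row_for("chembl_id", chembl_id)
            if (is.null(r)) return(NULL)
            a <- .parse_pka_field(r$pka_acidic)
            b <- .parse_pka_field(r$pka_basic)
            if (!length(a) && !length(b)) NULL
            else list(acidic = a, basic = b)
        })
}

#' Resolve one KEGG compound along the identifier chain
#'
#' Walks KEGG -> PubChem substance (SID) -> neutral-form compound
#' (CID, SMILES, formula, molecular weight) -> ChEMBL -> predicted per-group
#' pKa values through the supplied fetcher. An unresolvable link leaves every
#' downstream field absent (`NA`), never invented; a transport failure
#' propagates as a retryable `fiamrm_transport_error` and no partial record
#' is returned.
#'
#' @param kegg_id KEGG compound identifier ("C" + 5 digits)
#' @param fetcher an identifier-resolution contract, e.g. [tableFetcher()]
#' @return one-row data.frame in canonical library form
#' @examples
#' tab <- data.frame(kegg_id = "C00082", pubchem_sid = "3480",
#'                   pubchem_cid = "6057", chembl_id = "CHEMBL925",
#'                   name = "Tyrosine", smiles = "N[C@@H](Cc1ccc(O)cc1)C(O)=O",
#'                   formula = "C9H11NO3", mw = 181.19,
#'                   pka_acidic = "2.24;9.04", pka_basic = "9.52")
#' resolveChain("C00082", tableFetcher(tab))
#' @export
resolveChain <- function(kegg_id, fetcher) {
    if (!is.character(kegg_id) || length(kegg_id) != 1L ||
        !grepl("^C[0-9]{5}$", kegg_id))
        .input_error(sprintf("malformed KEGG compound id: %s",
                             paste(kegg_id, collapse = ",")))
    rec <- .empty_record()[0, ]
    rec[1, "kegg_id"] <- kegg_id
    rec$mw <- NA_real_; rec$has_stereo <- NA
    sid <- fetcher$sid_for_kegg(kegg_id)
    rec$pubchem_sid <- sid
    if (!is.na(sid)) {
        cid <- fetcher$cid_for_sid(sid)
        rec$pubchem_cid <- cid
        if (!is.na(cid)) {
            s <- fetcher$structure_for_cid(cid)
            if (!is.null(s)) {
                rec$smiles <- s$smiles
                rec$formula <- s$formula
                rec$mw <- s$mw
                rec$name <- s$name
                rec$has_stereo <- .has_stereo(s$smiles)
            }
            chembl <- fetcher$chembl_for_cid(cid)
            rec$chembl_id <- chembl
            if (!is.na(chembl)) {
                p <- fetcher$pka_for_chembl(chembl)
                if (!is.null(p)) {
                    rec$pka_acidic <- .join_pka_field(p$acidic)
                    rec$pka_basic <- .join_pka_field(p$basic)
                }
            }
        }
    }
    rownames(rec) <- NULL
    rec
}

.chain_stats <- function(rec) {
    with_sid <- !is.na(rec$pubchem_sid)
    with_cid <- with_sid & !is.na(rec$pubchem_cid)
    with_chembl <- with_cid & !is.na(rec$chembl_id)
    with_pka <- with_chembl &
        (!is.na(rec$pka_acidic) | !is.na(rec$pka_basic))
    setNames(as.integer(c(nrow(rec), sum(with_sid), sum(with_cid),
                          sum(with_chembl), sum(with_pka))),
             .LIBRARY_STAGES)
}

#' Build a compound library from resolved records
#'
#' Collapses duplicate `kegg_id` rows (first occurrence wins, with a
#' warning) and computes the survivor count at each stage of the
#' identifier-resolution chain. Stage counts are conjunctive along the
#' chain, so they are non-increasing by construction.
#'
#' @param records data.frame of canonical-form records (rows from
#'   [resolveChain()] or a records TSV); may be empty.
#' @return a [CompoundLibrary-class]
#' @export
buildLibrary <- function(records) {
    if (is.null(records) || nrow(records) == 0L)
        return(new("CompoundLibrary", records = .empty_record(),
                   stats = setNames(integer(5), .LIBRARY_STAGES)))
    records <- records[, .LIBRARY_COLUMNS]
    dup <- duplicated(records$kegg_id)
    if (any(dup)) {
        warning(sprintf("%d duplicate kegg_id record(s) dropped (first occurrence wins): %s",
                        sum(dup),
                        paste(unique(records$kegg_id[dup]), collapse = ", ")))
        records <- records[!dup, , drop = FALSE]
    }
    rownames(records) <- NULL
    new("CompoundLibrary", records = records, stats = .chain_stats(records))
}

.format_field <- function(x) {
    if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
    else if (is.numeric(x)) ifelse(is.na(x), "", as.character(x))
    else ifelse(is.na(x), "", x)
}

#' Read and write compound libraries as TSV
#'
#' The on-disk format is a UTF-8 TSV with the fixed canonical header
#' (`kegg_id`, `pubchem_sid`, `pubchem_cid`, `chembl_id`, `name`, `smiles`,
#' `formula`, `mw`, `has_stereo`, `pka_acidic`, `pka_basic`); absent values
#' are empty fields and pKa lists are ";"-joined. Write-read-write
#' round-trips are byte-identical.
#'
#' @param x a [CompoundLibrary-class]
#' @param path file path
#' @return `writeLibrary` returns `path` invisibly; `readLibrary` a
#'   [CompoundLibrary-class]
#' @export
writeLibrary <- function(x, path) {
    rec <- libraryRecords(x)
    out <- as.data.frame(lapply(rec, .format_field),
                         stringsAsFactors = FALSE)
    colnames(out) <- .LIBRARY_COLUMNS
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(.LIBRARY_COLUMNS, collapse = "\t"), con)
    if (nrow(out))
        writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
    invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
    raw <- read.delim(path, colClasses = "character", na.strings = "",
                      check.names = FALSE)
    if (!identical(colnames(raw), .LIBRARY_COLUMNS))
        .input_error("not a compound-library TSV (header mismatch)")
    raw$mw <- as.numeric(raw$mw)
    raw$has_stereo <- as.logical(raw$has_stereo)
    buildLibrary(raw)
}

#' Organism model: the metabolite set of a genome-scale model
#'
#' Captures the KEGG-derived view of one organism: pathways, genes, enzymes
#' and the compound identifiers reachable through them. Only
#' `metabolite_ids` drives method assembly; the remaining fields are carried
#' as provenance.
#'
#' @param org_code KEGG organism code (e.g. "sce")
#' @param metabolite_ids character vector of KEGG compound IDs
#' @param pathways,genes,enzymes optional provenance vectors
#' @return list of class `OrganismModel`
#' @export
organismModel <- function(org_code, metabolite_ids, pathways = character(),
                          genes = character(), enzymes = character()) {
    metabolite_ids <- unique(as.character(metabolite_ids))
    bad <- metabolite_ids[!grepl("^C[0-9]{5}$", metabolite_ids)]
    if (length(bad))
        .input_error(sprintf("syntactically invalid metabolite IDs: %s",
                             paste(bad, collapse = ", ")))
    structure(list(org_code = org_code, pathways = pathways, genes = genes,
                   enzymes = enzymes, metabolite_ids = metabolite_ids),
              class = "OrganismModel")
}

#' Restrict a library to an organism's metabolome
#'
#' Returns exactly the library records whose `kegg_id` occurs in the
#' organism model. Model metabolites absent from the library are reported in
#' the `missing` attribute (and a message), never an error.
#'
#' @param model an [organismModel()]
#' @param library a [CompoundLibrary-class]
#' @return data.frame of matching records with attribute `missing`
#' @export
organismMetabolome <- function(model, library) {
    stopifnot(inherits(model, "OrganismModel"))
    rec <- libraryRecords(library)
    keep <- rec$kegg_id %in% model$metabolite_ids
    missing <- setdiff(model$metabolite_ids, rec$kegg_id)
    if (length(missing))
        message(sprintf("%d organism metabolite(s) not in library: %s",
                        length(missing),
                        paste(head(missing, 10), collapse = ", ")))
    out <- rec[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "missing") <- missing
    out
}

#' Read and write organism models as TSV
#'
#' Two columns: `org_code`, `kegg_id` (one row per metabolite).
#' @param model an [organismModel()]
#' @param path file path
#' @export
writeOrganismModel <- function(model, path) {
    df <- data.frame(org_code = model$org_code,
                     kegg_id = model$metabolite_ids)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("org_code\tkegg_id", con)
    if (nrow(df))
        writeLines(paste(df$org_code, df$kegg_id, sep = "\t"), con)
    invisible(path)
}

#' @rdname writeOrganismModel
#' @export
readOrganismModel <- function(path) {
    df <- read.delim(path, colClasses = "character")
    organismModel(df$org_code[1], df$kegg_id)
}

#' Minimal live fetcher over the public REST interfaces
#'
#' Sketch of a network-backed implementation of the fetcher contract using
#' base-R connections against the KEGG and PubChem REST endpoints. It is
#' optional plumbing for interactive use: offline workflows and all tests
#' use table-backed fetchers ([tableFetcher()]), and pKa retrieval requires
#' a ChEMBL client and is therefore answered "absent" here.
#'
#' @return a fetcher list (see [tableFetcher()])
#' @export
restFetcher <- function() {
    get_lines <- function(url) {
        tryCatch(readLines(url, warn = FALSE),
                 error = function(e) .transport_error(conditionMessage(e)))
    }
    list(
        sid_for_kegg = function(kegg_id) {
            ln <- get_lines(sprintf("https://rest.kegg.jp/conv/pubchem/cpd:%s",
                                    kegg_id))
            if (!length(ln)) return(NA_character_)
            sub("^pubchem:", "", strsplit(ln[1], "\t")[[1]][2])
        },
        cid_for_sid = function(sid) {
            ln <- get_lines(sprintf(
                "https://pubchem.ncbi.nlm.nih.gov/rest/pug/substance/sid/%s/cids/TXT?cids_type=standardized",
                sid))
            if (!length(ln) || !nzchar(ln[1])) NA_character_ else ln[1]
        },
        structure_for_cid = function(cid) {
            ln <- get_lines(sprintf(
                "https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/cid/%s/property/CanonicalSMILES,IsomericSMILES,MolecularFormula,MolecularWeight,Title/CSV",
                cid))
            if (length(ln) < 2L) return(NULL)
            v <- read.csv(text = ln, colClasses = "character")
            list(smiles = v$IsomericSMILES[1], formula = v$MolecularFormula[1],
                 mw = as.numeric(v$MolecularWeight[1]), name = v$Title[1])
        },
        chembl_for_cid = function(cid) NA_character_,
        pka_for_chembl = function(chembl_id) NULL)
}
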