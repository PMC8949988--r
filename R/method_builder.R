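## Assembly of organism-specific MRM method packages: metabolite filtering,
## enantiomer deduplication, candidate-transition gathering with origin
## priority (in-house > literature > predicted), instrument-parameter
## defaults, isobaric-convolution detection, transition/mode selection,
## balanced packaging and injection-batch design.

.PROTON <- 1.007276  # Th, mass of a proton; precursor = MW +/- proton

#' Method-builder configuration
#'
#' Defaults follow the automated-method-development settings: precursor
#' molecular weight window 30-1500 g/mol, 5 % minimal relative signal for
#' predicted fragments, entrance potential 10 V and cell exit potential 4 V
#' when missing, 50 ms dwell time and at most 40 transitions per method
#' package (one package = one 1-min flow injection).
#'
#' @param mw_min,mw_max molecular-weight window, g/mol (strict inequalities)
#' @param min_rel_signal minimal relative signal of predicted fragments, %
#' @param default_ep entrance potential used when absent, V
#' @param default_cxp cell exit potential used when absent, V
#' @param dwell dwell time per transition, ms
#' @param max_per_package maximum transitions per method package
#' @param iso_tol m/z tolerance for isobaric-convolution detection, Th
#'   (0.5 Th: unit-resolution triple-quadrupole)
#' @return list of class `BuilderConfig`
#' @export
builderConfig <- function(mw_min = 30, mw_max = 1500, min_rel_signal = 5,
                          default_ep = 10, default_cxp = 4, dwell = 50,
                          max_per_package = 40, iso_tol = 0.5) {
    stopifnot(mw_min < mw_max, max_per_package >= 1, dwell > 0)
    structure(list(mw_min = mw_min, mw_max = mw_max,
                   min_rel_signal = min_rel_signal, default_ep = default_ep,
                   default_cxp = default_cxp, dwell = dwell,
                   max_per_package = max_per_package, iso_tol = iso_tol),
              class = "BuilderConfig")
}

#' Filter organism metabolites by molecular weight and classifiability
#'
#' Keeps records with `mw_min < mw < mw_max` whose pKa set yields a species
#' class other than unclassified; the class is annotated in a
#' `species_class` column. Records without pKa information carry no
#' ionization-mode evidence and are dropped.
#'
#' @param records data.frame of library records (organism-filtered)
#' @param config a [builderConfig()]
#' @param thresholds a [classifierThresholds()]
#' @return the retained records with an added `species_class` column
#' @export
filterMetabolites <- function(records, config = builderConfig(),
                              thresholds = classifierThresholds()) {
    if (!nrow(records)) {
        records$species_class <- character()
        return(records)
    }
    cls <- vapply(seq_len(nrow(records)), function(i) {
        classifySpecies(recordPka(records[i, , drop = FALSE]), thresholds)
    }, character(1))
    keep <- !is.na(records$mw) & records$mw > config$mw_min &
        records$mw < config$mw_max & cls != "unclassified"
    out <- records[keep, , drop = FALSE]
    out$species_class <- cls[keep]
    rownames(out) <- NULL
    out
}

.strip_stereo <- function(smiles) gsub("[@/\\\\]", "", smiles)

#' Collapse enantiomers to a single representative
#'
#' Records sharing molecular formula and molecular weight whose structure
#' strings differ only by stereochemistry descriptors are collapsed to one
#' record, deterministically keeping the smallest `kegg_id`. Structural
#' isomers (distinct stereo-stripped structures) are all kept.
#'
#' @param records data.frame of library records with `formula`, `mw` and
#'   `smiles` columns
#' @return deduplicated records
#' @export
dedupEnantiomers <- function(records) {
    if (nrow(records) < 2L) return(records)
    stripped <- ifelse(is.na(records$smiles), records$kegg_id,
                       .strip_stereo(records$smiles))
    key <- paste(records$formula, format(records$mw, digits = 10), stripped,
                 sep = "\r")
    ord <- order(key, records$kegg_id)
    out <- records[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    out <- out[order(match(out$kegg_id, records$kegg_id)), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fit the declustering-potential interpolation model
#'
#' Ordinary least-squares line of declustering potential over precursor
#' molecular weight, fitted per ionization mode on the in-house and
#' literature entries where DP is known; a mode with fewer than two points
#' falls back to the pooled fit. Used to fill missing DP values of
#' predicted transitions.
#'
#' @param known data.frame with columns `mode`, `mw`, `dp`
#' @return object of class `DpModel`; see [predictDp()]
#' @export
fitDpModel <- function(known) {
    known <- known[!is.na(known$dp) & !is.na(known$mw), , drop = FALSE]
    if (nrow(known) < 2L)
        .input_error("need at least two known declustering potentials")
    fit_line <- function(d) {
        if (length(unique(d$mw)) == 1L)  # degenerate: constant model
            c(intercept = mean(d$dp), slope = 0)
        else {
            cf <- coef(lm(dp ~ mw, data = d))
            c(intercept = unname(cf[1]), slope = unname(cf[2]))
        }
    }
    pooled <- fit_line(known)
    per_mode <- lapply(split(known, known$mode), function(d) {
        if (nrow(d) >= 2L) fit_line(d) else NULL
    })
    structure(list(pooled = pooled,
                   per_mode = per_mode[!vapply(per_mode, is.null,
                                               logical(1))]),
              class = "DpModel")
}

#' @rdname fitDpModel
#' @param model a `DpModel`
#' @param mw precursor molecular weight(s), g/mol
#' @param mode ionization mode(s), recycled against `mw`
#' @return predicted declustering potential(s), V
#' @export
predictDp <- function(model, mw, mode) {
    stopifnot(inherits(model, "DpModel"))
    n <- max(length(mw), length(mode))
    mw <- rep_len(mw, n); mode <- rep_len(mode, n)
    vapply(seq_len(n), function(i) {
        cf <- model$per_mode[[mode[i]]]
        if (is.null(cf)) cf <- model$pooled
        unname(cf["intercept"] + cf["slope"] * mw[i])
    }, numeric(1))
}

.precursor_mz <- function(mw, mode) {
    mw + ifelse(mode == "positive", .PROTON, -.PROTON)
}

#' Gather candidate transitions for every metabolite and allowed mode
#'
#' Applies the origin priority: for each metabolite and allowed ionization
#' mode, in-house transitions are used when available, otherwise literature
#' transitions, otherwise fragments of the predicted spectra (thresholded at
#' `min_rel_signal`, pooled over the three collision energies, deduplicated
#' by product m/z keeping the most intense occurrence, ranked by intensity).
#' Missing entrance/cell-exit potentials get the configured defaults,
#' missing declustering potentials the [fitDpModel()] interpolation, and
#' dwell time comes from the configuration. Metabolites with no candidate in
#' any allowed mode are reported in the `dropped` attribute.
#'
#' @param records filtered records (from [filterMetabolites()], with
#'   `species_class`)
#' @param inhouse,literature data.frames with columns `kegg_id`, `mode`,
#'   `q1`, `q3`, `ce`, `dp`, `ep`, `cxp` (NA allowed in the potentials);
#'   rows per metabolite/mode are taken as preference-ordered
#' @param predicted list of predicted `Spectrum` objects (see
#'   [parseCfmid()])
#' @param config a [builderConfig()]
#' @return data.frame of candidate transitions (`kegg_id`, `name`, `mode`,
#'   `deferred`, `q1`, `q3`, `ce`, `dp`, `ep`, `cxp`, `dwell`, `origin`,
#'   `intensity_rank`, `rel_intensity`) with attribute `dropped`
#' @export
assembleCandidates <- function(records, inhouse = NULL, literature = NULL,
                               predicted = list(),
                               config = builderConfig()) {
    empty_tab <- data.frame(kegg_id = character(), mode = character(),
                            q1 = numeric(), q3 = numeric(), ce = numeric(),
                            dp = numeric(), ep = numeric(), cxp = numeric())
    if (is.null(inhouse)) inhouse <- empty_tab
    if (is.null(literature)) literature <- empty_tab
    dp_known <- rbind(
        data.frame(mode = inhouse$mode, q1 = inhouse$q1, dp = inhouse$dp),
        data.frame(mode = literature$mode, q1 = literature$q1,
                   dp = literature$dp))
    dp_known <- dp_known[!is.na(dp_known$dp), , drop = FALSE]
    dp_model <- if (nrow(dp_known) >= 2L)
        fitDpModel(data.frame(mode = dp_known$mode, mw = dp_known$q1,
                              dp = dp_known$dp)) else NULL

    pred_by_key <- split(predicted, vapply(predicted, function(s)
        paste(s$compound_id, s$polarity), character(1)))

    rows <- list(); dropped <- character()
    for (i in seq_len(nrow(records))) {
        rec <- records[i, , drop = FALSE]
        alloc <- allocateMode(rec$species_class, recordPka(rec))
        got_any <- FALSE
        for (mode in alloc$modes) {
            tab_rows <- NULL; origin <- NULL
            ih <- inhouse[inhouse$kegg_id == rec$kegg_id &
                          inhouse$mode == mode, , drop = FALSE]
            li <- literature[literature$kegg_id == rec$kegg_id &
                             literature$mode == mode, , drop = FALSE]
            if (nrow(ih)) { tab_rows <- ih; origin <- "inhouse" }
            else if (nrow(li)) { tab_rows <- li; origin <- "literature" }
            if (!is.null(tab_rows)) {
                n <- nrow(tab_rows)
                rows[[length(rows) + 1L]] <- data.frame(
                    kegg_id = rec$kegg_id, name = rec$name, mode = mode,
                    deferred = alloc$deferred,
                    q1 = tab_rows$q1, q3 = tab_rows$q3, ce = tab_rows$ce,
                    dp = tab_rows$dp, ep = tab_rows$ep, cxp = tab_rows$cxp,
                    dwell = config$dwell, origin = origin,
                    intensity_rank = seq_len(n),
                    rel_intensity = 100 * (n - seq_len(n) + 1) / n)
                got_any <- TRUE
                next
            }
            specs <- pred_by_key[[paste(rec$kegg_id, mode)]]
            if (is.null(specs) || is.na(rec$mw)) next
            frags <- do.call(rbind, lapply(specs, function(s) {
                s <- applyThreshold(s, config$min_rel_signal)
                if (!nrow(s$peaks)) return(NULL)
                data.frame(q3 = s$peaks$mz, intensity = s$peaks$intensity,
                           rel_intensity = s$peaks$rel_intensity,
                           ce = s$collision_energy)
            }))
            if (is.null(frags) || !nrow(frags)) next
            q1 <- .precursor_mz(rec$mw, mode)
            frags <- frags[frags$q3 <= q1 + config$iso_tol, , drop = FALSE]
            if (!nrow(frags)) next
            frags <- frags[order(-frags$intensity), , drop = FALSE]
            frags <- frags[!duplicated(frags$q3), , drop = FALSE]
            rows[[length(rows) + 1L]] <- data.frame(
                kegg_id = rec$kegg_id, name = rec$name, mode = mode,
                deferred = alloc$deferred, q1 = q1, q3 = frags$q3,
                ce = frags$ce, dp = NA_real_, ep = NA_real_, cxp = NA_real_,
                dwell = config$dwell, origin = "predicted",
                intensity_rank = seq_len(nrow(frags)),
                rel_intensity = frags$rel_intensity)
            got_any <- TRUE
        }
        if (!got_any) dropped <- c(dropped, rec$kegg_id)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(kegg_id = character(), name = character(),
                   mode = character(), deferred = logical(), q1 = numeric(),
                   q3 = numeric(), ce = numeric(), dp = numeric(),
                   ep = numeric(), cxp = numeric(), dwell = numeric(),
                   origin = character(), intensity_rank = integer(),
                   rel_intensity = numeric())
    if (nrow(out)) {
        out$ep[is.na(out$ep)] <- config$default_ep
        out$cxp[is.na(out$cxp)] <- config$default_cxp
        miss_dp <- is.na(out$dp)
        if (any(miss_dp)) {
            if (is.null(dp_model))
                .input_error("missing DP values but no known DP to interpolate from")
            out$dp[miss_dp] <- predictDp(dp_model, out$q1[miss_dp],
                                         out$mode[miss_dp])
        }
        # CE sign must match the polarity
        out$ce <- ifelse(out$mode == "positive", abs(out$ce), -abs(out$ce))
    }
    rownames(out) <- NULL
    if (length(dropped))
        message(sprintf("%d metabolite(s) with no candidate transition dropped: %s",
                        length(dropped), paste(dropped, collapse = ", ")))
    attr(out, "dropped") <- dropped
    out
}

.convolved_flags <- function(candidates, iso_tol) {
    n <- nrow(candidates)
    flags <- logical(n)
    if (n < 2L) return(flags)
    for (m in unique(candidates$mode)) {
        idx <- which(candidates$mode == m)
        q1 <- candidates$q1[idx]; q3 <- candidates$q3[idx]
        id <- candidates$kegg_id[idx]
        for (a in seq_along(idx)) {
            hit <- abs(q1 - q1[a]) <= iso_tol & abs(q3 - q3[a]) <= iso_tol &
                id != id[a]
            if (any(hit)) flags[idx[a]] <- TRUE
        }
    }
    flags
}

#' Detect isobaric convolution groups among candidate transitions
#'
#' Mode-aware: two candidates convolve only if they share the ionization
#' mode and agree on both precursor (Q1) and product (Q3) m/z within
#' `iso_tol`; identical masses in opposite modes are not convolutions.
#' Groups are connected components (single linkage) containing at least two
#' distinct metabolites.
#'
#' @param candidates candidate table from [assembleCandidates()]
#' @param iso_tol m/z tolerance, Th
#' @return list of groups, each `list(mode, q1, q3, members)` where `q1`/
#'   `q3` are group means and `members` the distinct KEGG ids
#' @export
detectConvolutions <- function(candidates, iso_tol = 0.5) {
    groups <- list()
    for (m in unique(candidates$mode)) {
        idx <- which(candidates$mode == m)
        k <- length(idx)
        if (k < 2L) next
        comp <- seq_len(k)  # union-find over candidates of this mode
        find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
        q1 <- candidates$q1[idx]; q3 <- candidates$q3[idx]
        for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
            if (abs(q1[a] - q1[b]) <= iso_tol &&
                abs(q3[a] - q3[b]) <= iso_tol) {
                ra <- find(a); rb <- find(b)
                if (ra != rb) comp[rb] <- ra
            }
        }
        roots <- vapply(seq_len(k), find, integer(1))
        for (r in unique(roots)) {
            sel <- idx[roots == r]
            members <- unique(candidates$kegg_id[sel])
            if (length(members) >= 2L)
                groups[[length(groups) + 1L]] <-
                    list(mode = m, q1 = mean(candidates$q1[sel]),
                         q3 = mean(candidates$q3[sel]), members = members)
        }
    }
    groups
}

#' Select one transition and final ionization mode per metabolite
#'
#' For every metabolite the highest-ranked (most intense) candidate that is
#' free of isobaric convolutions in its mode is preferred. Dual-mode
#' (deferred) metabolites choose the mode that offers a convolution-free
#' candidate; when both modes do, the mode whose best candidate has the
#' higher predicted relative intensity wins, with a residual tie going to
#' negative mode. Only when no convolution-free candidate exists anywhere is
#' the top-ranked candidate taken and flagged `convolved`.
#'
#' @param candidates candidate table from [assembleCandidates()]
#' @param iso_tol m/z tolerance used for convolution detection, Th
#' @return data.frame with one selected transition per metabolite and a
#'   logical `convolved` column
#' @export
selectTransitions <- function(candidates, iso_tol = 0.5) {
    if (!nrow(candidates)) {
        candidates$convolved <- logical()
        return(candidates)
    }
    candidates$convolved <- .convolved_flags(candidates, iso_tol)
    best_in <- function(df) df[order(df$intensity_rank), , drop = FALSE][1, ,
                                                                drop = FALSE]
    pick <- function(df) {
        free <- df[!df$convolved, , drop = FALSE]
        modes <- unique(df$mode)
        if (nrow(free)) {
            free_modes <- unique(free$mode)
            if (length(free_modes) > 1L) {
                # both modes convolution-free: higher best rel. intensity,
                # residual tie -> negative
                bests <- lapply(split(free, free$mode), best_in)
                ri <- vapply(bests, function(b) b$rel_intensity, numeric(1))
                ord <- order(-ri, names(bests) != "negative")
                bests[[ord[1]]]
            } else best_in(free)
        } else {
            sel <- do.call(rbind, lapply(split(df, df$mode), best_in))
            sel <- sel[order(sel$intensity_rank, -sel$rel_intensity,
                             sel$mode != "negative"), , drop = FALSE]
            sel[1, , drop = FALSE]
        }
    }
    out <- do.call(rbind, lapply(split(candidates, candidates$kegg_id), pick))
    rownames(out) <- NULL
    out[order(out$kegg_id), , drop = FALSE]
}

#' Distribute selected transitions into balanced method packages
#'
#' Per ionization mode, the package count is `ceiling(n / max_per_package)`
#' and sizes are balanced to differ by at most one. Assignment is
#' deterministic: transitions are sorted by Q1 and dealt round-robin, so
#' package i of k holds every k-th transition of the sorted list.
#'
#' @param selected selection table from [selectTransitions()]
#' @param config a [builderConfig()]
#' @return an [MrmMethodSet-class]
#' @export
packageMethods <- function(selected, config = builderConfig()) {
    packages <- list()
    for (m in c("positive", "negative")) {
        sel <- selected[selected$mode == m, , drop = FALSE]
        n <- nrow(sel)
        if (!n) next
        k <- ceiling(n / config$max_per_package)
        sel <- sel[order(sel$q1, sel$kegg_id), , drop = FALSE]
        assign <- rep_len(seq_len(k), n)
        for (p in seq_len(k)) {
            pkg <- sel[assign == p, , drop = FALSE]
            rownames(pkg) <- NULL
            attr(pkg, "mode") <- m
            attr(pkg, "index") <- p
            packages[[length(packages) + 1L]] <- pkg
        }
    }
    new("MrmMethodSet", selection = selected, packages = packages,
        config = unclass(config))
}

#' End-to-end method assembly
#'
#' Convenience wrapper running [filterMetabolites()], [dedupEnantiomers()],
#' [assembleCandidates()], [selectTransitions()] and [packageMethods()] in
#' order on an organism-restricted record set.
#'
#' @inheritParams assembleCandidates
#' @param thresholds a [classifierThresholds()]
#' @return an [MrmMethodSet-class]
#' @export
buildMethodSet <- function(records, inhouse = NULL, literature = NULL,
                           predicted = list(), config = builderConfig(),
                           thresholds = classifierThresholds()) {
    recs <- filterMetabolites(records, config, thresholds)
    recs <- dedupEnantiomers(recs)
    cand <- assembleCandidates(recs, inhouse, literature, predicted, config)
    sel <- selectTransitions(cand, config$iso_tol)
    packageMethods(sel, config)
}

.METHOD_COLUMNS <- c("Q1", "Q3", "Time(msec)", "ID", "DP", "EP", "CE", "CXP")

#' Write instrument-format method tables
#'
#' Emits one CSV per package with columns exactly
#' `Q1, Q3, Time(msec), ID, DP, EP, CE, CXP`; `Time(msec)` is the dwell time
#' and `ID` combines the KEGG id with the readable name. Files are named
#' `method_<mode>_<index>.csv`. Write-read-write round trips are
#' byte-identical.
#'
#' @param mset an [MrmMethodSet-class]
#' @param dir output directory (created if needed)
#' @return character vector of file paths, invisibly
#' @export
formatMethodTables <- function(mset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    for (pkg in methodPackages(mset)) {
        tab <- data.frame(
            Q1 = as.character(pkg$q1), Q3 = as.character(pkg$q3),
            `Time(msec)` = as.character(pkg$dwell),
            ID = paste(pkg$kegg_id, pkg$name),
            DP = as.character(pkg$dp), EP = as.character(pkg$ep),
            CE = as.character(pkg$ce), CXP = as.character(pkg$cxp),
            check.names = FALSE)
        path <- file.path(dir, sprintf("method_%s_%d.csv",
                                       attr(pkg, "mode"),
                                       attr(pkg, "index")))
        con <- file(path, open = "wb")
        writeLines(paste(.METHOD_COLUMNS, collapse = ","), con)
        if (nrow(tab))
            writeLines(do.call(paste, c(unname(tab), sep = ",")), con)
        close(con)
        paths <- c(paths, path)
    }
    invisible(paths)
}

#' Read an emitted instrument method table
#'
#' @param path a CSV written by [formatMethodTables()]
#' @return data.frame with the instrument column contract
#' @export
readMethodTable <- function(path) {
    tab <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (!identical(colnames(tab), .METHOD_COLUMNS))
        .input_error("not an instrument method table (column mismatch)")
    for (col in c("Q1", "Q3", "Time(msec)", "DP", "EP", "CE", "CXP"))
        tab[[col]] <- as.numeric(tab[[col]])
    tab
}

#' Build the injection sequence for both polarities
#'
#' Each plate (one per polarity; samples are allocated identically to both)
#' starts with a blank and a QC injection, followed by the seed-shuffled
#' sample injections with a QC inserted after every 6 samples; a closing QC
#' is appended when the final block is incomplete. Sample injections are the
#' sample ids repeated `replicates` times before shuffling.
#'
#' @param samples character vector of sample ids
#' @param replicates technical replicates per sample
#' @param seed RNG seed; the same seed reproduces the same order
#' @param n_blanks leading blanks per plate
#' @return data.frame with columns `plate`, `polarity`, `position`, `type`,
#'   `sample_id`
#' @export
buildInjectionSequence <- function(samples, replicates = 1, seed = 1,
                                   n_blanks = 1) {
    inj <- rep(samples, each = replicates)
    shuffled <- .with_seed(seed, if (length(inj)) sample(inj) else inj)
    plate <- function(pol, plate_no) {
        type <- c(rep("blank", n_blanks), "qc")
        sid <- c(rep(NA_character_, n_blanks), NA_character_)
        for (i in seq_along(shuffled)) {
            type <- c(type, "sample"); sid <- c(sid, shuffled[i])
            if (i %% 6L == 0L) {
                type <- c(type, "qc"); sid <- c(sid, NA_character_)
            }
        }
        if (length(shuffled) && length(shuffled) %% 6L != 0L) {
            type <- c(type, "qc"); sid <- c(sid, NA_character_)
        }
        data.frame(plate = plate_no, polarity = pol,
                   position = seq_along(type), type = type, sample_id = sid)
    }
    out <- rbind(plate("positive", 1L), plate("negative", 2L))
    # the polarity change between plates runs behind a 30-min dummy method;
    # recorded as metadata only (no injections of its own)
    attr(out, "polarity_switch") <- "30 min dummy method between plates"
    out
}
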