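## Synthetic-fixture generators: every input the workflow consumes (compound
## library with pKa structure, organism model, predicted-spectrum documents,
## in-house/literature transition tables, peak-area batches with planted
## drift, class effects and missingness) can be generated deterministically
## from a seed, so the full tool is testable offline.

#' Fixture specification
#'
#' Defaults mirror the study design the workflow targets: three sample
#' classes (yeast-extract products) with six technical replicates each, QC
#' injections every six samples, multiplicative lognormal peak-area noise
#' (10 % CV), a smooth intra-batch drift of 20 % amplitude, 100 monitored
#' metabolites of which 10 are planted two-fold discriminators, sparse
#' missingness at random plus one whole-class knockout, and a S/N
#' distribution leaving a small fraction of cells at or below the S/N 5
#' threshold.
#'
#' @param seed RNG seed; a fixed seed gives byte-identical outputs
#' @param n_metabolites library size for [genLibrary()]
#' @param n_classes,n_per_class sample design for [genBatch()]
#' @param n_variables monitored metabolites in the batch
#' @param n_discriminators planted discriminating metabolites
#' @param fold_change effect size of a planted discriminator
#' @param noise_cv coefficient of variation of the lognormal noise
#' @param drift_model "sinusoid", "linear" or "none"
#' @param drift_amplitude drift amplitude as a fraction of the mean
#' @param mar_rate missing-at-random cell rate in sample injections
#' @param mnar_knockouts metabolites with one entire class knocked out
#' @param weak_rate fraction of metabolites near the detection limit
#'   (S/N clustered at/below the threshold in every injection; these are
#'   what the QC acceptance filter is meant to remove)
#' @param sn_dropout_rate sporadic per-cell low-S/N rate in otherwise
#'   well-measured metabolites
#' @param n_lead_qc lead-in QC injections before the first sample (batch
#'   equilibration), in addition to the QC after every sixth sample
#' @return list of class `FixtureSpec`
#' @export
fixtureSpec <- function(seed = 1, n_metabolites = 50, n_classes = 3,
                        n_per_class = 6, n_variables = 100,
                        n_discriminators = 10, fold_change = 2,
                        noise_cv = 0.1, drift_model = "sinusoid",
                        drift_amplitude = 0.2, mar_rate = 0.02,
                        mnar_knockouts = 1, weak_rate = 0.05,
                        sn_dropout_rate = 0.005, n_lead_qc = 3) {
    stopifnot(mar_rate >= 0, mar_rate <= 1, weak_rate >= 0, weak_rate <= 1,
              sn_dropout_rate >= 0, sn_dropout_rate <= 1,
              n_discriminators <= n_variables)
    structure(as.list(environment()), class = "FixtureSpec")
}

.kegg_id <- function(i) sprintf("C%05d", i)

#' Generate a synthetic compound library and organism model
#'
#' The library spans all five ionization species classes (acid, base,
#' amphoteric, neutral, unclassified), straddles the 30 and 1500 g/mol
#' molecular-weight bounds, and plants one enantiomer pair (identical
#' formula/MW, stereo-mirrored SMILES) and one isobaric pair per ionization
#' mode (identical MW and, via [genPredictedSpectra()], identical top
#' fragment). The organism model covers every library metabolite plus two
#' identifiers absent from the library (to exercise miss reporting).
#'
#' @param spec a [fixtureSpec()]
#' @return list with `records` (canonical library data.frame), `model`
#'   (an [organismModel()]) and `meta` (planted-feature bookkeeping:
#'   `species_class` per id, `enantiomer_pair`, `isobaric_pairs`,
#'   `spectrum_key` used to derive fragment sets)
#' @export
genLibrary <- function(spec = fixtureSpec()) {
    n <- spec$n_metabolites
    stopifnot(n >= 12)
    .with_seed(spec$seed, {
        ids <- .kegg_id(seq_len(n))
        cls <- rep(c("acid", "base", "amphoteric", "neutral",
                     "unclassified"), length.out = n)
        mw <- round(runif(n, 80, 600), 2)
        mw[1] <- 18.02    # below the 30 g/mol cut
        mw[2] <- 1600.5   # above the 1500 g/mol cut
        formula <- sprintf("C%dH%dN%dO%d", sample(2:20, n, TRUE),
                           sample(4:30, n, TRUE), sample(0:4, n, TRUE),
                           sample(1:8, n, TRUE))
        smiles <- sprintf("CC(N)C(=O)O%s", strrep("C", seq_len(n) %% 7))
        pka_a <- rep(NA_character_, n); pka_b <- rep(NA_character_, n)
        for (i in seq_len(n)) {
            set <- switch(cls[i],
                acid = list(a = round(sort(runif(sample(1:2, 1), 1, 6)), 2),
                            b = if (runif(1) < 0.3)
                                round(runif(1, 2, 8.4), 2) else numeric()),
                base = list(a = if (runif(1) < 0.3)
                                round(runif(1, 6.6, 12), 2) else numeric(),
                            b = round(runif(1, 8.6, 12), 2)),
                amphoteric = list(a = round(runif(1, 1, 5), 2),
                                  b = round(runif(1, 9, 11), 2)),
                neutral = if (runif(1) < 0.5)
                    list(a = round(runif(1, 6.6, 10), 2), b = numeric())
                else list(a = numeric(), b = round(runif(1, 3, 8.4), 2)),
                unclassified = list(a = numeric(), b = numeric()))
            pka_a[i] <- .join_pka_field(set$a)
            pka_b[i] <- .join_pka_field(set$b)
        }
        # enantiomer pair: two amphoteric records, same formula and MW,
        # SMILES differing only in stereo descriptors
        ena <- which(cls == "amphoteric")[1:2]
        formula[ena[2]] <- formula[ena[1]]
        mw[ena[2]] <- mw[ena[1]]
        smiles[ena] <- c("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O")
        pka_a[ena[2]] <- pka_a[ena[1]]; pka_b[ena[2]] <- pka_b[ena[1]]
        # isobaric pairs: same MW (structural isomers, distinct stripped
        # SMILES); genPredictedSpectra gives them the same fragment key
        iso_neg <- which(cls == "acid")[2:3]
        iso_pos <- which(cls == "base")[2:3]
        for (pair in list(iso_neg, iso_pos)) {
            mw[pair[2]] <- mw[pair[1]]
            smiles[pair] <- c("OCC1OC(O)C(O)C1O", "OC1COC(O)C(O)C1O")
        }
        has_chembl <- cls != "unclassified"
        records <- data.frame(
            kegg_id = ids,
            pubchem_sid = as.character(100000 + seq_len(n)),
            pubchem_cid = as.character(5000 + seq_len(n)),
            chembl_id = ifelse(has_chembl,
                               sprintf("CHEMBL%d", 7000 + seq_len(n)),
                               NA_character_),
            name = sprintf("metabolite_%03d", seq_len(n)),
            smiles = smiles, formula = formula, mw = mw,
            has_stereo = .has_stereo(smiles),
            pka_acidic = pka_a, pka_basic = pka_b,
            stringsAsFactors = FALSE)
        spectrum_key <- seq_len(n)
        spectrum_key[iso_neg[2]] <- spectrum_key[iso_neg[1]]
        spectrum_key[iso_pos[2]] <- spectrum_key[iso_pos[1]]
        model <- organismModel("syn", c(ids, .kegg_id(n + 1:2)))
        list(records = records, model = model,
             meta = list(species_class = setNames(cls, ids),
                         enantiomer_pair = ids[ena],
                         isobaric_pairs = list(negative = ids[iso_neg],
                                               positive = ids[iso_pos]),
                         spectrum_key = setNames(spectrum_key, ids)))
    })
}

#' Generate predicted-spectrum documents in the CFM-ID text dialect
#'
#' One document per metabolite and allowed ionization mode, with the three
#' energy blocks (`energy0`/`energy1`/`energy2`), a known base peak shared
#' across blocks and at least one planted peak below the 5 % relative-signal
#' threshold per document. Metabolites of a planted isobaric pair share
#' their fragment set, so their top transitions coincide.
#'
#' @param spec a [fixtureSpec()]
#' @param lib result of [genLibrary()]
#' @return named list (`"<kegg_id> <mode>"`) of character vectors, each a
#'   parseable document for [parseCfmid()]
#' @export
genPredictedSpectra <- function(spec, lib) {
    records <- lib$records; meta <- lib$meta
    docs <- list()
    for (i in seq_len(nrow(records))) {
        id <- records$kegg_id[i]
        cls <- meta$species_class[[id]]
        pka <- recordPka(records[i, , drop = FALSE])
        if (cls == "unclassified") next
        modes <- tryCatch(allocateMode(cls, pka)$modes,
                          error = function(e) character())
        for (mode in modes) {
            q1 <- .precursor_mz(records$mw[i], mode)
            key <- meta$spectrum_key[[id]] * 2L +
                (mode == "positive")
            frag <- .with_seed(spec$seed * 1000L + key, {
                n_frag <- sample(4:8, 1)
                mz <- round(sort(runif(n_frag, 0.15 * q1, 0.95 * q1)), 2)
                rel <- c(100, round(runif(n_frag - 1, 6, 90), 1))
                list(mz = mz, rel = rel,
                     sub = round(runif(1, 0.05 * q1, 0.95 * q1), 2))
            })
            block <- function(scale) {
                ints <- round(frag$rel * scale, 3)
                c(paste(frag$mz, ints),
                  paste(frag$sub, round(2 * scale, 3)))  # 2 % of base peak
            }
            docs[[paste(id, mode)]] <- c(
                "energy0", block(1.0),
                "energy1", block(0.8),
                "energy2", block(0.5))
        }
    }
    docs
}

#' Write predicted-spectrum documents to files
#'
#' @param docs result of [genPredictedSpectra()]
#' @param dir output directory; files are named `<kegg_id>_<mode>.txt`
#' @return file paths, invisibly
#' @export
writeCfmidFiles <- function(docs, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(docs), function(key) {
        parts <- strsplit(key, " ", fixed = TRUE)[[1]]
        path <- file.path(dir, sprintf("%s_%s.txt", parts[1], parts[2]))
        con <- file(path, open = "wb")
        writeLines(docs[[key]], con)
        close(con)
        path
    }, character(1))
    invisible(paths)
}

#' Parse generated (or real) predicted-spectrum documents into spectra
#'
#' @param docs named list as from [genPredictedSpectra()] (names
#'   `"<kegg_id> <mode>"`)
#' @return flat list of predicted `Spectrum` objects
#' @export
parseSpectrumDocs <- function(docs) {
    out <- list()
    for (key in names(docs)) {
        parts <- strsplit(key, " ", fixed = TRUE)[[1]]
        out <- c(out, parseCfmid(docs[[key]], compound_id = parts[1],
                                 polarity = parts[2]))
    }
    out
}

#' Generate in-house and literature transition tables
#'
#' Covers a slice of the classifiable metabolites with preference-ordered
#' transitions carrying known declustering potentials (so the DP
#' interpolation model is estimable); entrance and cell-exit potentials are
#' partly missing to exercise the defaults.
#'
#' @param spec a [fixtureSpec()]
#' @param lib result of [genLibrary()]
#' @param frac_inhouse,frac_literature fraction of classifiable metabolites
#'   covered by each origin
#' @return list with data.frames `inhouse` and `literature`
#' @export
genTransitionTables <- function(spec, lib, frac_inhouse = 0.3,
                                frac_literature = 0.3) {
    records <- lib$records; meta <- lib$meta
    ok <- records$kegg_id[meta$species_class[records$kegg_id] !=
                          "unclassified"]
    # planted isobaric pairs stay predicted-only so their fragment-set
    # coincidence survives the origin priority
    ok <- setdiff(ok, unlist(meta$isobaric_pairs))
    .with_seed(spec$seed + 77L, {
        n_ih <- ceiling(frac_inhouse * length(ok))
        n_li <- ceiling(frac_literature * length(ok))
        picked <- sample(ok, min(length(ok), n_ih + n_li))
        make <- function(ids) {
            rows <- lapply(ids, function(id) {
                i <- match(id, records$kegg_id)
                cls <- meta$species_class[[id]]
                pka <- recordPka(records[i, , drop = FALSE])
                modes <- allocateMode(cls, pka)$modes
                do.call(rbind, lapply(modes, function(mode) {
                    q1 <- .precursor_mz(records$mw[i], mode)
                    k <- sample(1:2, 1)
                    data.frame(kegg_id = id, mode = mode, q1 = round(q1, 2),
                               q3 = round(runif(k, 0.2, 0.9) * q1, 2),
                               ce = sample(c(10, 20, 40), k, TRUE) *
                                   ifelse(mode == "positive", 1, -1),
                               dp = round(20 + 0.15 * q1 +
                                          rnorm(k, 0, 2), 1),
                               ep = ifelse(runif(k) < 0.5, 10, NA_real_),
                               cxp = ifelse(runif(k) < 0.5, 4, NA_real_))
                }))
            })
            do.call(rbind, rows)
        }
        list(inhouse = make(picked[seq_len(min(n_ih, length(picked)))]),
             literature = make(picked[seq_len(length(picked)) > n_ih]))
    })
}

.drift_factor <- function(order, spec) {
    if (spec$drift_model == "none" || spec$drift_amplitude == 0)
        return(rep(1, length(order)))
    t <- (order - min(order)) / max(1, diff(range(order)))
    switch(spec$drift_model,
           linear = 1 + spec$drift_amplitude * (t - 0.5),
           sinusoid = 1 + spec$drift_amplitude * sin(2 * pi * t),
           .input_error("unknown drift model"))
}

#' Generate a peak-area batch with planted structure
#'
#' Emulates one DS-FIA-MRM measurement batch: a lead blank, lead-in QC
#' injections (pooled class means) followed by seeded-shuffled sample
#' injections with a QC after every sixth sample, multiplicative lognormal
#' noise, a smooth injection-order drift, planted fold-change
#' discriminators, missing-at-random cells and whole-class
#' (missing-not-at-random) knockouts. Signal-to-noise is modelled as a
#' compound property: a `weak_rate` fraction of metabolites sits at the
#' detection limit in every injection (the population the QC acceptance
#' filter removes), while well-measured metabolites suffer only sporadic
#' per-cell dropouts. Planted effects are placed in well-measured
#' metabolites - only measurable variables can carry recoverable structure.
#'
#' @param spec a [fixtureSpec()]
#' @param analytes optional analyte names (default `M001`..)
#' @return an [MrmExperiment-class]; planted structure is recorded in
#'   `metadata(.)$planted` (`discriminators` with their up-class,
#'   `mnar_metabolites` with their knocked-out class, `weak_metabolites`,
#'   `drift`)
#' @export
genBatch <- function(spec = fixtureSpec(), analytes = NULL) {
    p <- spec$n_variables
    if (is.null(analytes)) analytes <- sprintf("M%03d", seq_len(p))
    stopifnot(length(analytes) == p)
    classes <- paste0("YE", seq_len(spec$n_classes))
    .with_seed(spec$seed + 13L, {
        sample_ids <- unlist(lapply(classes, function(k)
            paste0(k, "_r", seq_len(spec$n_per_class))))
        shuffled <- sample(sample_ids)
        type <- c("blank", rep("qc", spec$n_lead_qc))
        sid <- rep(NA_character_, length(type))
        for (i in seq_along(shuffled)) {
            type <- c(type, "sample"); sid <- c(sid, shuffled[i])
            if (i %% 6L == 0L) { type <- c(type, "qc"); sid <- c(sid, NA) }
        }
        if (length(shuffled) %% 6L != 0L) {
            type <- c(type, "qc"); sid <- c(sid, NA)
        }
        n_inj <- length(type)
        cls_of <- ifelse(type == "sample", sub("_r[0-9]+$", "", sid),
                         NA_character_)
        base_mean <- rlnorm(p, log(1e5), 0.5)
        weak <- sample(seq_len(p), round(spec$weak_rate * p))
        measurable <- setdiff(seq_len(p), weak)
        disc <- sample(measurable, spec$n_discriminators)
        up_class <- sample(classes, spec$n_discriminators, replace = TRUE)
        class_mean <- matrix(rep(base_mean, spec$n_classes), p,
                             spec$n_classes,
                             dimnames = list(analytes, classes))
        for (d in seq_along(disc))
            class_mean[disc[d], up_class[d]] <-
                class_mean[disc[d], up_class[d]] * spec$fold_change
        pooled <- rowMeans(class_mean)
        drift <- .drift_factor(seq_len(n_inj), spec)
        sdlog <- sqrt(log(1 + spec$noise_cv^2))
        area <- matrix(NA_real_, p, n_inj,
                       dimnames = list(analytes, NULL))
        for (j in seq_len(n_inj)) {
            mu <- switch(type[j],
                         blank = rep(NA_real_, p),
                         qc = pooled,
                         sample = class_mean[, cls_of[j]])
            if (type[j] != "blank")
                area[, j] <- mu * drift[j] *
                    rlnorm(p, -sdlog^2 / 2, sdlog)
        }
        # S/N: compound-level sensitivity plus sporadic per-cell dropouts
        sn <- matrix(NA_real_, p, n_inj, dimnames = dimnames(area))
        nonblank <- type != "blank"
        sn[, nonblank] <- rlnorm(p * sum(nonblank), log(60), 0.4)
        sn[weak, nonblank] <- rlnorm(length(weak) * sum(nonblank),
                                     log(4), 0.5)
        drop_cells <- which(nonblank[col(sn)] &
                            !(row(sn) %in% weak) &
                            runif(p * n_inj) < spec$sn_dropout_rate)
        sn[drop_cells] <- runif(length(drop_cells), 0.5, 5)
        # MAR missingness in sample cells of measurable metabolites
        smp <- which(type == "sample")
        mar <- which(runif(p * n_inj) < spec$mar_rate &
                     (col(area) %in% smp) & !(row(area) %in% weak))
        area[mar] <- NA_real_
        # MNAR: whole-class knockouts in measurable non-discriminators
        mnar_ids <- character(); mnar_class <- character()
        if (spec$mnar_knockouts > 0) {
            cand <- setdiff(measurable, disc)
            knock <- sample(cand, min(spec$mnar_knockouts, length(cand)))
            for (r in knock) {
                k <- sample(classes, 1)
                area[r, which(type == "sample" & cls_of == k)] <- NA_real_
                mnar_class <- c(mnar_class, k)
            }
            mnar_ids <- analytes[knock]
        }
        mx <- MrmExperiment(area, sn, injection_order = seq_len(n_inj),
                            type = type, class = cls_of,
                            sample_id = ifelse(is.na(sid), type, sid))
        metadata(mx)$planted <- list(
            discriminators = setNames(up_class, analytes[disc]),
            mnar_metabolites = setNames(mnar_class, mnar_ids),
            weak_metabolites = analytes[weak],
            drift = drift)
        mx
    })
}

#' Worked prediction-validation example
#'
#' A constructed measured/predicted spectrum pair with 8 measured peaks,
#' 18 predicted peaks and exactly 6 shared m/z values at +20 V, the
#' configuration whose validation metrics are recall 75 %, precision
#' 33.3 % and Jaccard score 30 %.
#'
#' @return list with `measured` and `predicted` `Spectrum` objects
#' @export
genValidationExample <- function() {
    shared <- c(91.05, 95.05, 119.05, 123.04, 136.08, 165.05)
    meas_only <- c(77.04, 147.04)
    pred_only <- c(51.02, 53.04, 65.04, 74.02, 81.03, 93.07, 103.05,
                   107.05, 117.06, 121.06, 133.05, 149.02)
    measured <- msSpectrum(c(shared, meas_only),
                           c(100, 12, 45, 8, 95, 30, 9, 14),
                           compound_id = "C00082", polarity = "positive",
                           collision_energy = 20, source = "measured")
    predicted <- msSpectrum(c(shared, pred_only),
                            c(80, 10, 50, 6, 100, 25,
                              rep(c(5, 9, 13), length.out = 12)),
                            compound_id = "C00082", polarity = "positive",
                            collision_energy = 20, source = "predicted")
    list(measured = measured, predicted = predicted)
}

#' Emit a complete demo workspace
#'
#' Writes every input the workflow consumes to `dir`: `library.tsv`,
#' `model.tsv`, a `spectra/` directory of predicted-spectrum documents,
#' `inhouse.tsv`, `literature.tsv` and `batch.csv`.
#'
#' @param dir output directory
#' @param spec a [fixtureSpec()]
#' @return `dir`, invisibly
#' @export
genDemoWorkspace <- function(dir, spec = fixtureSpec()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    lib <- genLibrary(spec)
    writeLibrary(buildLibrary(lib$records), file.path(dir, "library.tsv"))
    writeOrganismModel(lib$model, file.path(dir, "model.tsv"))
    writeCfmidFiles(genPredictedSpectra(spec, lib),
                    file.path(dir, "spectra"))
    tabs <- genTransitionTables(spec, lib)
    for (nm in c("inhouse", "literature")) {
        tab <- tabs[[nm]]
        out <- as.data.frame(lapply(tab, .format_field))
        con <- file(file.path(dir, paste0(nm, ".tsv")), open = "wb")
        writeLines(paste(colnames(tab), collapse = "\t"), con)
        writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
        close(con)
    }
    writeFeatureTable(genBatch(spec), file.path(dir, "batch.csv"))
    invisible(dir)
}
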