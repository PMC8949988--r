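rec_row <- function(kegg_id, mw, formula = "C6H12O6", smiles = "OCC(O)C=O",
                    pka_acidic = "2.5", pka_basic = NA_character_,
                    name = kegg_id) {
    data.frame(kegg_id = kegg_id, pubchem_sid = "1", pubchem_cid = "2",
               chembl_id = "CHEMBL1", name = name, smiles = smiles,
               formula = formula, mw = mw,
               has_stereo = grepl("[@/\\\\]", smiles),
               pka_acidic = pka_acidic, pka_basic = pka_basic,
               stringsAsFactors = FALSE)
}

test_that("metabolite filtering applies the MW window and classifiability", {
    recs <- rbind(rec_row("C00001", 18),                      # below 30
                  rec_row("C00002", 180.16, pka_acidic = "2.3",
                          pka_basic = "9.7"),                 # amphoteric
                  rec_row("C00003", 1500),                    # boundary out
                  rec_row("C00004", 250, pka_acidic = NA,
                          pka_basic = NA))                    # unclassified
    recs$chembl_id[4] <- NA
    kept <- filterMetabolites(recs)
    expect_equal(kept$kegg_id, "C00002")
    expect_equal(kept$species_class, "amphoteric")
})

test_that("enantiomer pairs collapse to the smallest KEGG id", {
    dl <- rbind(rec_row("C00133", 89.09, "C3H7NO2", "C[C@@H](N)C(=O)O"),
                rec_row("C00041", 89.09, "C3H7NO2", "C[C@H](N)C(=O)O"))
    out <- dedupEnantiomers(dl)
    expect_equal(out$kegg_id, "C00041")
    # structural isomers with the same formula both survive
    iso <- rbind(rec_row("C00221", 180.16, "C6H12O6", "OCC1OC(O)C(O)C1O"),
                 rec_row("C00936", 180.16, "C6H12O6", "OC1COC(O)C(O)C1O"))
    expect_equal(nrow(dedupEnantiomers(iso)), 2L)
    expect_equal(nrow(dedupEnantiomers(iso[1, ])), 1L)
})

test_that("declustering-potential model interpolates linearly", {
    m <- fitDpModel(data.frame(mode = "positive", mw = c(100, 300),
                               dp = c(40, 80)))
    expect_equal(predictDp(m, 200, "positive"), 60)
    # constant DP -> constant model
    mc <- fitDpModel(data.frame(mode = "negative", mw = c(100, 200, 400),
                                dp = 55))
    expect_equal(predictDp(mc, 999, "negative"), 55)
    # seeded points vs the normal-equation oracle
    set.seed(12)
    mw <- runif(15, 80, 600)
    dp <- 20 + 0.1 * mw + rnorm(15, 0, 3)
    fit <- fitDpModel(data.frame(mode = "positive", mw = mw, dp = dp))
    sxx <- sum((mw - mean(mw))^2)
    slope_o <- sum((mw - mean(mw)) * (dp - mean(dp))) / sxx
    int_o <- mean(dp) - slope_o * mean(mw)
    expect_equal(predictDp(fit, 0, "positive"), int_o, tolerance = 1e-10)
    expect_equal(predictDp(fit, 1, "positive") - predictDp(fit, 0,
                                                           "positive"),
                 slope_o, tolerance = 1e-10)
    # a mode with < 2 points falls back to the pooled fit
    expect_equal(predictDp(fit, 100, "negative"),
                 predictDp(fit, 100, "positive"))
    expect_error(fitDpModel(data.frame(mode = "positive", mw = 100,
                                       dp = 40)),
                 class = "fiamrm_input_error")
})

test_that("candidate assembly honours origin priority and defaults", {
    recs <- filterMetabolites(rbind(
        rec_row("C00010", 200, pka_acidic = "2.0"),
        rec_row("C00020", 300, pka_acidic = "2.0")))
    inhouse <- data.frame(kegg_id = "C00010", mode = "negative",
                          q1 = c(199, 199), q3 = c(90, 110),
                          ce = c(-25, -30), dp = c(60, 62),
                          ep = NA_real_, cxp = NA_real_)
    doc <- c("energy0", "100 100", "150 50", "energy1", "100 80",
             "energy2", "100 40")
    pred <- c(parseCfmid(doc, "C00010", "negative"),
              parseCfmid(doc, "C00020", "negative"))
    cand <- assembleCandidates(recs, inhouse = inhouse, predicted = pred)
    c10 <- cand[cand$kegg_id == "C00010", ]
    expect_true(all(c10$origin == "inhouse"))   # in-house beats predicted
    expect_true(all(c10$ep == 10) && all(c10$cxp == 4))  # defaults filled
    expect_true(all(c10$dwell == 50))
    c20 <- cand[cand$kegg_id == "C00020", ]
    expect_true(all(c20$origin == "predicted"))
    expect_true(all(c20$ce %in% c(-10, -20, -40)))
    expect_equal(c20$q1, rep(300 - 1.007276, nrow(c20)))
    # pooled ranking: the base peak (present at all three CEs) is rank 1
    expect_equal(c20$q3[c20$intensity_rank == 1], 100)
    # negative-mode CE carries a negative sign
    expect_true(all(c20$ce < 0))
})

test_that("convolution detection is mode-aware and tolerance-bounded", {
    hex <- rbind(cand_row("C00001", "negative", 259.02, 97.0),
                 cand_row("C00002", "negative", 259.02, 97.0))
    groups <- detectConvolutions(hex, 0.5)
    expect_length(groups, 1L)
    expect_setequal(groups[[1]]$members, c("C00001", "C00002"))
    # identical masses in opposite modes do not convolve
    cross <- rbind(cand_row("C00001", "negative", 259.02, 97.0),
                   cand_row("C00002", "positive", 259.02, 97.0))
    expect_length(detectConvolutions(cross, 0.5), 0L)
    # just outside tolerance
    apart <- rbind(cand_row("C00001", "negative", 259.02, 97.0),
                   cand_row("C00002", "negative", 259.02, 97.51))
    expect_length(detectConvolutions(apart, 0.5), 0L)
})

test_that("selection avoids convolutions when an alternative exists", {
    # rank-1 convolved with a neighbour, rank-2 free -> rank 2 chosen
    cand <- rbind(cand_row("C00001", "negative", 200, 90, rank = 1),
                  cand_row("C00001", "negative", 200, 120, rank = 2),
                  cand_row("C00002", "negative", 200, 90, rank = 1))
    sel <- selectTransitions(cand, 0.5)
    s1 <- sel[sel$kegg_id == "C00001", ]
    expect_equal(s1$q3, 120); expect_false(s1$convolved)
    # all candidates convolved -> rank 1 selected and labelled
    cand2 <- rbind(cand_row("C00001", "negative", 200, 90, rank = 1),
                   cand_row("C00002", "negative", 200, 90, rank = 1))
    sel2 <- selectTransitions(cand2, 0.5)
    expect_true(all(sel2$convolved))
    expect_equal(sel2$intensity_rank, c(1L, 1L))
    # deferred metabolite: positive candidate convolved, negative free
    cand3 <- rbind(cand_row("C00003", "positive", 150, 80, deferred = TRUE),
                   cand_row("C00003", "negative", 148, 70, deferred = TRUE),
                   cand_row("C00009", "positive", 150, 80))
    s3 <- selectTransitions(cand3, 0.5)
    expect_equal(s3$mode[s3$kegg_id == "C00003"], "negative")
    expect_false(s3$convolved[s3$kegg_id == "C00003"])
})

test_that("selection is optimal versus exhaustive enumeration", {
    set.seed(23)
    for (rep in 1:30) {
        n_met <- sample(2:6, 1)
        cand <- do.call(rbind, lapply(seq_len(n_met), function(i) {
            n_c <- sample(1:3, 1)
            modes <- sample(c("positive", "negative"), n_c, replace = TRUE)
            do.call(rbind, lapply(seq_len(n_c), function(j)
                cand_row(sprintf("C%05d", i), modes[j],
                         q1 = sample(seq(100, 120, 5), 1),
                         q3 = sample(seq(50, 70, 5), 1), rank = j,
                         rel = 100 - 10 * j)))
        }))
        sel <- selectTransitions(cand, 0.5)
        # oracle: a metabolite can be convolution-free iff any of its
        # candidates has no same-mode neighbour from another metabolite
        for (id in unique(cand$kegg_id)) {
            mine <- cand[cand$kegg_id == id, ]
            others <- cand[cand$kegg_id != id, ]
            free_any <- any(vapply(seq_len(nrow(mine)), function(r) {
                !any(others$mode == mine$mode[r] &
                     abs(others$q1 - mine$q1[r]) <= 0.5 &
                     abs(others$q3 - mine$q3[r]) <= 0.5)
            }, logical(1)))
            expect_equal(sel$convolved[sel$kegg_id == id], !free_any,
                         info = sprintf("rep %d id %s", rep, id))
        }
    }
})

test_that("selection prefers in-house origin whenever available", {
    recs <- filterMetabolites(rec_row("C00050", 200, pka_acidic = "2"))
    inhouse <- data.frame(kegg_id = "C00050", mode = "negative", q1 = 199,
                          q3 = 90, ce = -20, dp = 50, ep = 10, cxp = 4)
    doc <- c("energy0", "88 100", "energy1", "88 80", "energy2", "88 10")
    cand <- assembleCandidates(recs, inhouse = inhouse,
                               predicted = parseCfmid(doc, "C00050",
                                                      "negative"))
    sel <- selectTransitions(cand, 0.5)
    expect_equal(sel$origin, "inhouse")
})

test_that("packaging balances sizes and conserves metabolites", {
    mk_sel <- function(n, mode) {
        do.call(rbind, lapply(seq_len(n), function(i)
            cand_row(sprintf("%s%05d", if (mode == "positive") "P" else "N",
                             i), mode, q1 = 100 + i, q3 = 50 + i)))
    }
    sel <- rbind(mk_sel(96, "positive"), mk_sel(156, "negative"))
    sel$convolved <- FALSE
    ms <- packageMethods(sel, builderConfig())
    sizes <- vapply(methodPackages(ms), nrow, integer(1))
    modes <- vapply(methodPackages(ms), function(p) attr(p, "mode"),
                    character(1))
    expect_equal(sum(modes == "positive"), 3L)
    expect_equal(sum(modes == "negative"), 4L)
    expect_equal(sizes[modes == "positive"], rep(32L, 3))
    expect_equal(sizes[modes == "negative"], rep(39L, 4))
    expect_equal(sum(sizes), 252L)
    # conservation: every metabolite in exactly one package
    ids <- unlist(lapply(methodPackages(ms), function(p) p$kegg_id))
    expect_equal(sort(ids), sort(sel$kegg_id))
    # 41 -> 21 + 20
    ms41 <- packageMethods(within(mk_sel(41, "positive"),
                                  convolved <- FALSE))
    expect_equal(sort(vapply(methodPackages(ms41), nrow, integer(1)),
                      decreasing = TRUE), c(21L, 20L))
    # determinism
    ms2 <- packageMethods(sel, builderConfig())
    expect_identical(lapply(methodPackages(ms), `[[`, "kegg_id"),
                     lapply(methodPackages(ms2), `[[`, "kegg_id"))
})

test_that("package sizes respect the cap and balance for random inputs", {
    set.seed(41)
    for (rep in 1:20) {
        n <- sample(1:130, 1)
        sel <- do.call(rbind, lapply(seq_len(n), function(i)
            cand_row(sprintf("C%05d", i),
                     sample(c("positive", "negative"), 1),
                     q1 = runif(1, 50, 900), q3 = runif(1, 30, 800))))
        sel$convolved <- FALSE
        ms <- packageMethods(sel, builderConfig())
        sizes <- vapply(methodPackages(ms), nrow, integer(1))
        modes <- vapply(methodPackages(ms), function(p) attr(p, "mode"),
                        character(1))
        expect_true(all(sizes <= 40))
        expect_equal(sum(sizes), n)
        for (m in unique(modes)) {
            sz <- sizes[modes == m]
            expect_lte(diff(range(sz)), 1L)
            expect_equal(length(sz),
                         ceiling(sum(sz) / 40))
        }
    }
})

test_that("instrument tables use the exact column contract and round-trip", {
    sel <- rbind(cand_row("C00031", "negative", 179.05, 89.02),
                 cand_row("C00082", "positive", 182.08, 136.08))
    sel$convolved <- FALSE
    sel$name <- c("D-Glucose", "L-Tyrosine")
    ms <- packageMethods(sel, builderConfig())
    dir <- tempfile(); paths <- formatMethodTables(ms, dir)
    expect_length(paths, 2L)
    tab <- readMethodTable(paths[1])
    expect_identical(colnames(tab),
                     c("Q1", "Q3", "Time(msec)", "ID", "DP", "EP", "CE",
                       "CXP"))
    expect_true(all(tab$`Time(msec)` == 50))
    expect_match(tab$ID[1], "^C[0-9]{5} ")
    # byte-stable: write -> read -> write
    first <- readBin(paths[1], "raw", file.size(paths[1]))
    tab2 <- readMethodTable(paths[1])
    p2 <- tempfile(fileext = ".csv")
    con <- file(p2, "wb")
    writeLines(paste(colnames(tab2), collapse = ","), con)
    writeLines(do.call(paste, c(lapply(tab2, as.character), sep = ",")),
               con)
    close(con)
    expect_identical(first, readBin(p2, "raw", file.size(p2)))
})

test_that("injection sequences lead with blanks and insert QCs every 6", {
    seqs <- buildInjectionSequence(sprintf("S%02d", 1:12), replicates = 1,
                                   seed = 42)
    pos <- seqs[seqs$polarity == "positive", ]
    expect_equal(pos$type[1], "blank")
    expect_equal(pos$type[2], "qc")
    expect_equal(sum(pos$type == "qc"), 3L)  # 1 + floor(12 / 6)
    # never more than 6 consecutive samples
    runs <- rle(pos$type)
    expect_true(all(runs$lengths[runs$values == "sample"] <= 6))
    # determinism and identical allocation on both plates
    seqs2 <- buildInjectionSequence(sprintf("S%02d", 1:12), 1, seed = 42)
    expect_identical(seqs, seqs2)
    neg <- seqs[seqs$polarity == "negative", ]
    expect_identical(pos$sample_id, neg$sample_id)
    # degenerate run: blank + QC only
    empty <- buildInjectionSequence(character(), 1, seed = 1)
    expect_equal(empty$type[empty$polarity == "positive"], c("blank", "qc"))
    # replicates multiply injections
    rep2 <- buildInjectionSequence(c("A", "B"), replicates = 3, seed = 1)
    expect_equal(sum(rep2$type == "sample" & rep2$polarity == "positive"),
                 6L)
})

test_that("method assembly conserves metabolites end to end", {
    spec <- fixtureSpec(seed = 3)
    lib <- genLibrary(spec)
    l <- buildLibrary(lib$records)
    om <- suppressMessages(organismMetabolome(lib$model, l))
    specs <- parseSpectrumDocs(genPredictedSpectra(spec, lib))
    tabs <- genTransitionTables(spec, lib)
    ms <- buildMethodSet(om, tabs$inhouse, tabs$literature, specs)
    sel <- selectedTransitions(ms)
    ids <- unlist(lapply(methodPackages(ms), function(p) p$kegg_id))
    expect_setequal(ids, sel$kegg_id)
    expect_equal(length(ids), nrow(sel))
    expect_equal(anyDuplicated(ids), 0L)
    # analysis time in minutes equals the package count
    expect_equal(length(methodPackages(ms)),
                 sum(vapply(methodPackages(ms), nrow, integer(1)) > 0))
})
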