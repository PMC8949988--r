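# Shared fixture builders: everything is constructed in code.

# Fully-resolving identifier table for the tyrosine-like record plus a few
# partially resolvable neighbours.
fetcher_table <- function() {
    data.frame(
        kegg_id = c("C00082", "C00041", "C00188", "C00999"),
        pubchem_sid = c("3480", "3425", NA, "9001"),
        pubchem_cid = c("6057", "5950", NA, NA),
        chembl_id = c("CHEMBL925", NA, NA, NA),
        name = c("Tyrosine", "Alanine", NA, NA),
        smiles = c("N[C@@H](Cc1ccc(O)cc1)C(O)=O", "C[C@@H](N)C(=O)O",
                   NA, NA),
        formula = c("C9H11NO3", "C3H7NO2", NA, NA),
        mw = c(181.19, 89.09, NA, NA),
        pka_acidic = c("2.24;9.04", NA, NA, NA),
        pka_basic = c("9.52", NA, NA, NA),
        stringsAsFactors = FALSE)
}

# n canonical records with a controlled number of CID / pKa survivors.
make_records <- function(n, n_cid = n, n_pka = n) {
    if (n == 0) return(make_records(1)[0, ])
    stopifnot(n_pka <= n_cid, n_cid <= n)
    data.frame(
        kegg_id = sprintf("C%05d", seq_len(n)),
        pubchem_sid = as.character(1000 + seq_len(n)),
        pubchem_cid = ifelse(seq_len(n) <= n_cid,
                             as.character(2000 + seq_len(n)), NA),
        chembl_id = ifelse(seq_len(n) <= n_pka,
                           sprintf("CHEMBL%d", seq_len(n)), NA),
        name = sprintf("cmpd%02d", seq_len(n)),
        smiles = sprintf("CC(N)C(=O)O%s", strrep("C", seq_len(n) %% 5)),
        formula = sprintf("C%dH%dNO2", 2 + seq_len(n), 5 + seq_len(n)),
        mw = 80 + 10 * seq_len(n),
        has_stereo = FALSE,
        pka_acidic = ifelse(seq_len(n) <= n_pka, "3.1", NA),
        pka_basic = NA_character_,
        stringsAsFactors = FALSE)
}

# Minimal candidate row for transition-selection tests.
cand_row <- function(kegg_id, mode, q1, q3, rank = 1L, rel = 100,
                     deferred = FALSE) {
    data.frame(kegg_id = kegg_id, name = kegg_id, mode = mode,
               deferred = deferred, q1 = q1, q3 = q3,
               ce = if (mode == "positive") 20 else -20,
               dp = 60, ep = 10, cxp = 4, dwell = 50, origin = "predicted",
               intensity_rank = rank, rel_intensity = rel)
}

# Small experiment for the QC-pipeline unit tests: areas given per row,
# columns annotated by type/class.
make_mx <- function(area, type, class = rep(NA_character_, length(type)),
                    sn = NULL) {
    area <- as.matrix(area)
    if (is.null(rownames(area)))
        rownames(area) <- sprintf("M%02d", seq_len(nrow(area)))
    if (is.null(sn)) sn <- matrix(100, nrow(area), ncol(area))
    MrmExperiment(area, sn, injection_order = seq_len(ncol(area)),
                  type = type, class = class,
                  sample_id = paste0("inj", seq_len(ncol(area))))
}

# Random spectrum on a coarse m/z grid (spacing >> tolerance), so the
# greedy matcher and the exact set-intersection oracle must agree.
grid_spectrum <- function(n, polarity = "positive", ce = 20,
                          source = "measured") {
    mz <- sort(sample(seq(50, 500, by = 0.5), n))
    msSpectrum(mz, runif(n, 1, 100), polarity = polarity,
               collision_energy = ce, source = source)
}
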