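## Predicted-spectrum parsing (CFM-ID text dialect), relative-intensity
## thresholding, measured-vs-predicted peak matching and the five
## prediction-validation metrics (R, P, WR, WP, J).

.CE_LEVELS <- c(energy0 = 10, energy1 = 20, energy2 = 40)

#' Construct an MS/MS spectrum
#'
#' @param mz numeric vector of fragment mass-to-charge values (Th)
#' @param intensity matching intensities (arbitrary units)
#' @param compound_id compound identifier
#' @param polarity "positive" or "negative"
#' @param collision_energy collision energy in V; its sign must match the
#'   polarity (+ for positive, - for negative)
#' @param source "measured" or "predicted"
#' @return list of class `Spectrum`; peaks are sorted by mz and
#'   `rel_intensity` is percent of the base peak (exactly one peak at 100
#'   when non-empty)
#' @export
msSpectrum <- function(mz, intensity, compound_id = NA_character_,
                       polarity = c("positive", "negative"),
                       collision_energy = NA_real_,
                       source = c("measured", "predicted")) {
    polarity <- match.arg(polarity)
    source <- match.arg(source)
    stopifnot(length(mz) == length(intensity))
    if (length(mz) && (any(mz <= 0) || any(intensity <= 0)))
        .input_error("peak mz and intensity must be positive")
    o <- order(mz)
    peaks <- data.frame(mz = mz[o], intensity = intensity[o])
    peaks$rel_intensity <- if (nrow(peaks))
        100 * peaks$intensity / max(peaks$intensity) else numeric()
    structure(list(compound_id = compound_id, polarity = polarity,
                   collision_energy = collision_energy, source = source,
                   peaks = peaks),
              class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
    cat(sprintf("Spectrum %s [%s, %+g V, %s]: %d peaks\n",
                x$compound_id, x$polarity, x$collision_energy, x$source,
                nrow(x$peaks)))
    invisible(x)
}

#' Parse a CFM-ID-dialect predicted-spectrum document
#'
#' The dialect is three energy blocks headed `energy0`/`energy1`/`energy2`
#' (low/medium/high collision energy, mapped to +-10/+-20/+-40 V) whose body
#' lines are "mz intensity" pairs (trailing annotations ignored). One
#' spectrum is returned per block present; a missing block yields a partial
#' result with a warning, an unparsable line a parse error naming the line.
#'
#' @param text character vector of lines, or a single string with newlines
#' @param compound_id compound identifier for the returned spectra
#' @param polarity ionization mode of the prediction; determines the sign of
#'   the collision energy
#' @return list of `Spectrum` objects (source = "predicted")
#' @export
parseCfmid <- function(text, compound_id = NA_character_,
                       polarity = c("positive", "negative")) {
    polarity <- match.arg(polarity)
    if (length(text) == 1L && grepl("\n", text))
        text <- strsplit(text, "\n", fixed = TRUE)[[1]]
    lines <- trimws(text)
    keep <- nzchar(lines) & !startsWith(lines, "#")
    if (!any(keep)) .input_error("empty predicted-spectrum document")
    block <- NA_character_
    acc <- list()
    for (i in seq_along(lines)) {
        if (!keep[i]) next
        ln <- lines[i]
        if (ln %in% names(.CE_LEVELS)) {
            block <- ln
            if (is.null(acc[[block]]))
                acc[[block]] <- list(mz = numeric(), int = numeric())
            next
        }
        if (is.na(block))
            .input_error(sprintf("line %d: peak line before any energy block",
                                 i))
        fields <- strsplit(ln, "[[:space:]]+")[[1]]
        mz <- suppressWarnings(as.numeric(fields[1]))
        it <- suppressWarnings(as.numeric(fields[2]))
        if (length(fields) < 2L || is.na(mz) || is.na(it))
            .input_error(sprintf("line %d: cannot parse peak line '%s'",
                                 i, ln))
        acc[[block]]$mz <- c(acc[[block]]$mz, mz)
        acc[[block]]$int <- c(acc[[block]]$int, it)
    }
    missing <- setdiff(names(.CE_LEVELS), names(acc))
    if (length(missing))
        warning(sprintf("missing energy block(s): %s",
                        paste(missing, collapse = ", ")))
    sign <- if (polarity == "positive") 1 else -1
    lapply(names(acc), function(b) {
        msSpectrum(acc[[b]]$mz, acc[[b]]$int, compound_id = compound_id,
                   polarity = polarity,
                   collision_energy = sign * .CE_LEVELS[[b]],
                   source = "predicted")
    })
}

#' Remove peaks below a relative-intensity threshold
#'
#' Peaks with `rel_intensity` strictly below `min_rel` percent of the base
#' peak are removed; the base peak itself always survives. Re-thresholding
#' at the same level is idempotent.
#'
#' @param s a `Spectrum`
#' @param min_rel threshold in percent, in [0, 100)
#' @return the thresholded `Spectrum`
#' @export
applyThreshold <- function(s, min_rel = 5) {
    stopifnot(inherits(s, "Spectrum"), min_rel >= 0, min_rel < 100)
    keep <- s$peaks$rel_intensity >= min_rel
    out <- s
    out$peaks <- s$peaks[keep, , drop = FALSE]
    rownames(out$peaks) <- NULL
    out
}

#' Match a measured against a predicted spectrum
#'
#' Greedy nearest-mz pairing within an absolute tolerance: candidate pairs
#' are ranked by |delta mz|, ties broken toward the higher predicted
#' intensity, and accepted while both peaks are still unused, so each peak
#' appears in at most one pair.
#'
#' @param measured,predicted `Spectrum` objects with equal polarity and
#'   collision energy
#' @param tol absolute m/z tolerance in Th (default 0.01, high-resolution
#'   QqToF context)
#' @return list of class `MatchResult`: `matched` (data.frame of paired
#'   measured/predicted mz and intensity), `unmatched_measured`,
#'   `unmatched_predicted`, `tolerance`, `n_measured`, `n_predicted`
#' @export
matchSpectra <- function(measured, predicted, tol = 0.01) {
    stopifnot(inherits(measured, "Spectrum"), inherits(predicted, "Spectrum"))
    if (!identical(measured$polarity, predicted$polarity) ||
        !isTRUE(all.equal(measured$collision_energy,
                          predicted$collision_energy)))
        .input_error("polarity/collision-energy mismatch between spectra")
    pm <- measured$peaks; pp <- predicted$peaks
    cand <- expand.grid(i = seq_len(nrow(pm)), j = seq_len(nrow(pp)))
    if (nrow(cand)) {
        cand$dmz <- abs(pm$mz[cand$i] - pp$mz[cand$j])
        cand <- cand[cand$dmz <= tol, , drop = FALSE]
        cand <- cand[order(cand$dmz, -pp$intensity[cand$j]), , drop = FALSE]
    }
    used_i <- logical(nrow(pm)); used_j <- logical(nrow(pp))
    pairs <- list()
    for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
    idx <- if (length(pairs)) do.call(rbind, pairs) else
        matrix(integer(), 0, 2)
    matched <- data.frame(measured_mz = pm$mz[idx[, 1]],
                          measured_intensity = pm$intensity[idx[, 1]],
                          predicted_mz = pp$mz[idx[, 2]],
                          predicted_intensity = pp$intensity[idx[, 2]])
    structure(list(matched = matched,
                   unmatched_measured = pm[!used_i, , drop = FALSE],
                   unmatched_predicted = pp[!used_j, , drop = FALSE],
                   tolerance = tol,
                   n_measured = nrow(pm), n_predicted = nrow(pp)),
              class = "MatchResult")
}

#' Prediction-validation metrics of a spectral match
#'
#' Five fractions in [0, 1]: recall R = matched / measured peaks; precision
#' P = matched / predicted peaks; weighted recall WR = matched measured
#' intensity / total measured intensity; weighted precision WP = matched
#' predicted intensity / total predicted intensity; Jaccard score
#' J = matched / (measured + predicted - matched). Always J <= min(R, P).
#'
#' @param m a `MatchResult` from [matchSpectra()]
#' @return list of class `SpectrumMetrics` with elements `R`, `P`, `WR`,
#'   `WP`, `J`
#' @examples
#' me <- msSpectrum(c(91, 136, 165), c(40, 100, 20),
#'                  collision_energy = 20, source = "measured")
#' pr <- msSpectrum(c(91, 136, 119), c(30, 80, 10),
#'                  collision_energy = 20, source = "predicted")
#' spectrumMetrics(matchSpectra(me, pr, tol = 0.01))
#' @export
spectrumMetrics <- function(m) {
    stopifnot(inherits(m, "MatchResult"))
    if (m$n_measured == 0L || m$n_predicted == 0L)
        .input_error("metrics undefined for an empty spectrum")
    n_match <- nrow(m$matched)
    meas_total <- sum(m$matched$measured_intensity) +
        sum(m$unmatched_measured$intensity)
    pred_total <- sum(m$matched$predicted_intensity) +
        sum(m$unmatched_predicted$intensity)
    structure(list(
        R = n_match / m$n_measured,
        P = n_match / m$n_predicted,
        WR = sum(m$matched$measured_intensity) / meas_total,
        WP = sum(m$matched$predicted_intensity) / pred_total,
        J = n_match / (m$n_measured + m$n_predicted - n_match)),
        class = "SpectrumMetrics")
}

#' Summarize validation metrics by ionization mode and collision energy
#'
#' @param results data.frame with columns `polarity`, `ce` and the five
#'   metric columns `R`, `P`, `WR`, `WP`, `J` (one row per compound/spectrum
#'   comparison)
#' @return data.frame with one row per group ("all", each polarity, each
#'   absolute collision energy) and mean / standard error per metric;
#'   a group of one has standard error 0
#' @export
summarizeMetrics <- function(results) {
    metrics <- c("R", "P", "WR", "WP", "J")
    stopifnot(all(c("polarity", "ce", metrics) %in% colnames(results)))
    one <- function(label, rows) {
        out <- data.frame(group = label, n = nrow(rows))
        for (m in metrics) {
            out[[paste0(m, "_mean")]] <- mean(rows[[m]])
            out[[paste0(m, "_se")]] <- if (nrow(rows) > 1L)
                sd(rows[[m]]) / sqrt(nrow(rows)) else 0
        }
        out
    }
    groups <- list(one("all", results))
    for (p in sort(unique(results$polarity)))
        groups <- c(groups, list(one(paste0("mode:", p),
                                     results[results$polarity == p, ])))
    for (e in sort(unique(abs(results$ce))))
        groups <- c(groups, list(one(paste0("ce:", e),
                                     results[abs(results$ce) == e, ])))
    do.call(rbind, groups)
}

#' Read measured spectra from a TSV peak list
#'
#' Columns: `compound_id`, `polarity`, `ce`, `mz`, `intensity`; one
#' `Spectrum` is built per (compound_id, polarity, ce) group.
#' @param path file path
#' @return list of `Spectrum` objects (source = "measured")
#' @export
readMeasuredSpectra <- function(path) {
    df <- read.delim(path)
    key <- interaction(df$compound_id, df$polarity, df$ce, drop = TRUE)
    lapply(split(df, key), function(g) {
        msSpectrum(g$mz, g$intensity, compound_id = g$compound_id[1],
                   polarity = g$polarity[1], collision_energy = g$ce[1],
                   source = "measured")
    })
}
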