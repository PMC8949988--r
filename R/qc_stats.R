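## QC / chemometrics pipeline: S/N filtering -> QC-based LOESS drift
## correction -> QC acceptance -> imputation -> (range scaling inside CV)
## -> PCA / PLS-DA / Kruskal-Wallis -> variable selection. The stage order
## is part of the contract: every stage stamps the experiment and refuses
## to run after a later stage.

.PIPELINE_STAGES <- c(sn_filter = 1L, loess = 2L, qc_accept = 3L,
                      impute = 4L)

.stamp_stage <- function(mx, stage) {
    done <- metadata(mx)$pipeline_stages
    metadata(mx)$pipeline_stages <- union(done, stage)
    mx
}

.check_stage <- function(mx, stage) {
    done <- metadata(mx)$pipeline_stages
    later <- names(.PIPELINE_STAGES)[.PIPELINE_STAGES >
                                     .PIPELINE_STAGES[[stage]]]
    bad <- intersect(done, later)
    if (length(bad))
        .input_error(sprintf(
            "pipeline order violated: %s cannot run after %s",
            stage, paste(bad, collapse = ", ")))
}

#' QC and statistics configuration
#'
#' @param sn_min signal-to-noise threshold; cells with S/N not strictly
#'   above it are set missing
#' @param rsd_max maximal QC relative standard deviation, percent
#' @param qc_missing_max maximal missing fraction in QC injections, percent
#' @param alpha Kruskal-Wallis significance level
#' @param n_boot bootstrap resamples for confidence intervals
#' @param cv_folds folds of the stratified double cross-validation
#' @param q2_gain minimal Q2 gain (absolute) that justifies one more
#'   principal component / latent variable
#' @param vip_cut VIP threshold for variable selection (strictly greater)
#' @param beta_criterion "ci" (bootstrap CI excludes 0) or "point"
#'   (coefficient point estimate nonzero) for variable selection
#' @param p_adjust p-value adjustment method for the Kruskal-Wallis screen
#'   ("none" by default; "BH" available)
#' @param span_grid LOESS smoothing-span candidates for leave-one-out CV
#' @return list of class `QcConfig`
#' @export
qcConfig <- function(sn_min = 5, rsd_max = 20, qc_missing_max = 30,
                     alpha = 0.05, n_boot = 1000, cv_folds = 5,
                     q2_gain = 0.05, vip_cut = 1,
                     beta_criterion = c("ci", "point"), p_adjust = "none",
                     span_grid = seq(0.3, 1, by = 0.1)) {
    stopifnot(sn_min > 0, rsd_max > 0, qc_missing_max > 0, alpha > 0,
              n_boot >= 1, cv_folds >= 2, q2_gain > 0, vip_cut > 0)
    structure(list(sn_min = sn_min, rsd_max = rsd_max,
                   qc_missing_max = qc_missing_max, alpha = alpha,
                   n_boot = n_boot, cv_folds = cv_folds, q2_gain = q2_gain,
                   vip_cut = vip_cut,
                   beta_criterion = match.arg(beta_criterion),
                   p_adjust = p_adjust, span_grid = span_grid),
              class = "QcConfig")
}

#' Remove low signal-to-noise cells
#'
#' Areas whose S/N is not strictly greater than `sn_min` are set missing.
#'
#' @param mx an [MrmExperiment-class]
#' @param config a [qcConfig()]
#' @return the filtered experiment
#' @export
filterSn <- function(mx, config = qcConfig()) {
    .check_stage(mx, "sn_filter")
    area <- assay(mx, "area")
    sn <- assay(mx, "sn")
    area[!is.na(area) & (is.na(sn) | sn <= config$sn_min)] <- NA_real_
    assay(mx, "area") <- area
    .stamp_stage(mx, "sn_filter")
}

.rsd <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    100 * sd(v) / mean(v)
}

# Leave-one-out CV error of a degree-1 LOESS at one span; Inf when the
# smoother cannot be fitted at this span.
.loess_loo <- function(x, y, span) {
    err <- vapply(seq_along(x), function(i) {
        fit <- tryCatch(suppressWarnings(
            loess(y[-i] ~ x[-i], span = span, degree = 1,
                  family = "gaussian",
                  control = loess.control(surface = "direct"))),
            error = function(e) NULL)
        if (is.null(fit)) return(Inf)
        pred <- tryCatch(suppressWarnings(predict(fit, newdata = x[i])),
                         error = function(e) NA_real_)
        if (!is.finite(pred)) Inf else (pred - y[i])^2
    }, numeric(1))
    mean(err)
}

#' QC-anchored LOESS drift correction
#'
#' Per metabolite, a degree-1 (locally linear, tricube-weighted) LOESS of
#' the QC areas over injection order models the intra-batch drift; the
#' smoothing span is chosen from a fixed grid by leave-one-out
#' cross-validation on the QC injections. The trend is interpolated to every
#' injection and areas are corrected by `QC median / trend`. Metabolites
#' with fewer than 4 usable QC injections are skipped with a warning; a
#' trend that interpolates to a non-positive value, or a correction that
#' does not reduce the QC RSD, leaves the metabolite uncorrected (flagged in
#' the report).
#'
#' @param mx an [MrmExperiment-class]
#' @param config a [qcConfig()] (uses `span_grid`)
#' @return list with `experiment` (corrected) and `correction` (data.frame:
#'   `analyte`, `span`, `corrected`, `reason`, `rsd_raw`, `rsd_corrected`)
#' @export
loessCorrect <- function(mx, config = qcConfig()) {
    .check_stage(mx, "loess")
    area <- assay(mx, "area")
    is_qc <- sampleType(mx) == "qc"
    ord <- injectionOrder(mx)
    rows <- rownames(area)
    if (is.null(rows)) rows <- as.character(seq_len(nrow(area)))
    rep_list <- vector("list", nrow(area))
    for (r in seq_len(nrow(area))) {
        y_all <- area[r, ]
        qc_ok <- is_qc & !is.na(y_all)
        report <- data.frame(analyte = rows[r], span = NA_real_,
                             corrected = FALSE, reason = "",
                             rsd_raw = .rsd(y_all[is_qc]),
                             rsd_corrected = NA_real_)
        if (sum(qc_ok) < 4L) {
            warning(sprintf("analyte %s: fewer than 4 QC injections, drift correction skipped",
                            rows[r]))
            report$reason <- "too_few_qc"
            rep_list[[r]] <- report
            next
        }
        xq <- ord[qc_ok]; yq <- y_all[qc_ok]
        cv <- vapply(config$span_grid, function(s) .loess_loo(xq, yq, s),
                     numeric(1))
        if (!any(is.finite(cv))) {
            report$reason <- "loess_failed"
            rep_list[[r]] <- report
            next
        }
        span <- config$span_grid[which.min(cv)]
        fit <- suppressWarnings(
            loess(yq ~ xq, span = span, degree = 1, family = "gaussian",
                  control = loess.control(surface = "direct")))
        trend <- suppressWarnings(predict(fit, newdata = ord))
        report$span <- span
        if (any(!is.finite(trend) | trend <= 0)) {
            report$reason <- "nonpositive_trend"
            rep_list[[r]] <- report
            next
        }
        corrected <- y_all * median(yq) / trend
        rsd_new <- .rsd(corrected[is_qc])
        report$rsd_corrected <- rsd_new
        if (is.na(rsd_new) || is.na(report$rsd_raw) ||
            rsd_new > report$rsd_raw) {
            report$reason <- "no_rsd_improvement"
            rep_list[[r]] <- report
            next
        }
        area[r, ] <- corrected
        report$corrected <- TRUE
        rep_list[[r]] <- report
    }
    assay(mx, "area") <- area
    list(experiment = .stamp_stage(mx, "loess"),
         correction = do.call(rbind, rep_list))
}

#' QC acceptance of metabolites
#'
#' A metabolite is accepted when its QC relative standard deviation
#' (sample sd / mean over non-missing QC areas) is below `rsd_max` percent
#' and its missing fraction among QC injections is below `qc_missing_max`
#' percent.
#'
#' @param mx an [MrmExperiment-class]
#' @param config a [qcConfig()]
#' @return list with `experiment` (restricted to accepted metabolites,
#'   stamped) and `report` (data.frame: `analyte`, `qc_rsd`, `qc_missing`,
#'   `pass`)
#' @export
qcAccept <- function(mx, config = qcConfig()) {
    .check_stage(mx, "qc_accept")
    area <- assay(mx, "area")
    is_qc <- sampleType(mx) == "qc"
    if (sum(is_qc) < 2L)
        .input_error("QC acceptance needs at least two QC injections")
    qc_rsd <- apply(area[, is_qc, drop = FALSE], 1, .rsd)
    qc_missing <- 100 * rowMeans(is.na(area[, is_qc, drop = FALSE]))
    pass <- !is.na(qc_rsd) & qc_rsd < config$rsd_max &
        qc_missing < config$qc_missing_max
    rows <- rownames(area)
    if (is.null(rows)) rows <- as.character(seq_len(nrow(area)))
    report <- data.frame(analyte = rows, qc_rsd = qc_rsd,
                         qc_missing = qc_missing, pass = pass,
                         row.names = NULL)
    list(experiment = .stamp_stage(mx[pass, ], "qc_accept"),
         report = report)
}

#' Impute missing sample areas
#'
#' Per metabolite and sample class: if some replicates of the class are
#' present, missing cells are treated as missing at random and get the
#' class mean; if the entire class is missing, the cells are treated as
#' missing not at random (below detection) and get half of the metabolite's
#' global minimum over all sample injections. A metabolite missing in every
#' sample is dropped with a warning. Only sample injections are imputed.
#'
#' @param mx an [MrmExperiment-class] (QC-accepted)
#' @return the imputed experiment; the per-class imputation log is in
#'   `metadata(.)$imputation_log` (`analyte`, `class`, `rule`, `n_cells`)
#' @export
imputeMissing <- function(mx) {
    .check_stage(mx, "impute")
    area <- assay(mx, "area")
    is_sample <- sampleType(mx) == "sample"
    cls <- sampleClass(mx)
    rows <- rownames(area)
    if (is.null(rows)) rows <- as.character(seq_len(nrow(area)))
    log <- list()
    drop <- logical(nrow(area))
    for (r in seq_len(nrow(area))) {
        v <- area[r, ]
        sample_v <- v[is_sample]
        if (all(is.na(sample_v))) {
            drop[r] <- TRUE
            next
        }
        global_min <- min(sample_v, na.rm = TRUE)
        for (k in unique(cls[is_sample])) {
            in_k <- is_sample & cls == k & !is.na(cls)
            miss <- in_k & is.na(v)
            if (!any(miss)) next
            if (all(is.na(v[in_k]))) {            # MNAR: whole class absent
                v[miss] <- global_min / 2
                rule <- "MNAR_half_min"
            } else {                              # MAR: partial missingness
                v[miss] <- mean(v[in_k], na.rm = TRUE)
                rule <- "MAR_class_mean"
            }
            log[[length(log) + 1L]] <- data.frame(
                analyte = rows[r], class = k, rule = rule,
                n_cells = sum(miss))
        }
        area[r, ] <- v
    }
    if (any(drop))
        warning(sprintf("%d metabolite(s) missing in every sample dropped: %s",
                        sum(drop), paste(rows[drop], collapse = ", ")))
    assay(mx, "area") <- area
    mx <- mx[!drop, ]
    mx <- .stamp_stage(mx, "impute")
    metadata(mx)$imputation_log <- if (length(log)) do.call(rbind, log)
        else data.frame(analyte = character(), class = character(),
                        rule = character(), n_cells = integer())
    mx
}

#' Range scaling fitted on training data only
#'
#' Per variable, `(x - min_train) / (max_train - min_train)`; test data are
#' scaled with the training limits and are not clipped, so values outside
#' the training range map outside [0, 1]. Constant training columns are
#' flagged and scaled to 0.
#'
#' @param train numeric matrix, samples x variables
#' @param test optional matrix with the same columns
#' @return list with `train`, `test` (or `NULL`) and `limits` (data.frame
#'   `min`, `max`, `constant`)
#' @export
rangeScale <- function(train, test = NULL) {
    mn <- apply(train, 2, min); mxv <- apply(train, 2, max)
    rng <- mxv - mn
    constant <- rng == 0
    rng[constant] <- 1
    scale_one <- function(m) {
        out <- sweep(sweep(m, 2, mn), 2, rng, "/")
        out[, constant] <- 0
        out
    }
    list(train = scale_one(train),
         test = if (!is.null(test)) scale_one(test),
         limits = data.frame(min = mn, max = mxv, constant = constant))
}

#' PCA with cross-validated component selection
#'
#' Principal component analysis of the range-scaled sample matrix. R2X is
#' the cumulative explained variance; Q2X comes from a k-fold
#' cross-validation in which the scaling and the loadings are fitted on the
#' training split and the left-out rows are reconstructed from their
#' projections. The retained component count follows the gain rule: stop
#' when one more component improves Q2X by less than `q2_gain`.
#'
#' @param x numeric matrix, samples x metabolites (imputed)
#' @param config a [qcConfig()]
#' @param seed RNG seed for the fold assignment
#' @param ncomp_max largest component count examined
#' @return object of class `PcaModel`: `n_pc`, `scores`, `loadings`,
#'   `r2x_comp`, `r2x` (cumulative at `n_pc`), `q2x` (per count)
#' @export
fitPca <- function(x, config = qcConfig(), seed = 1, ncomp_max = NULL) {
    n <- nrow(x)
    rank_max <- min(n - 1L, ncol(x))
    if (is.null(ncomp_max)) ncomp_max <- min(10L, rank_max)
    ncomp_max <- min(ncomp_max, rank_max)
    folds <- min(config$cv_folds, n)
    fold_of <- .with_seed(seed, rep_len(seq_len(folds), n)[sample(n)])
    press <- matrix(0, folds, ncomp_max); tss <- numeric(folds)
    for (f in seq_len(folds)) {
        tr <- fold_of != f
        sc <- rangeScale(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
        ctr <- colMeans(sc$train)
        pc <- prcomp(sc$train, center = TRUE, scale. = FALSE)
        Xte <- sweep(sc$test, 2, ctr)
        tss[f] <- sum(Xte^2)
        for (a in seq_len(ncomp_max)) {
            aa <- min(a, ncol(pc$rotation))
            V <- pc$rotation[, seq_len(aa), drop = FALSE]
            press[f, a] <- sum((Xte - Xte %*% V %*% t(V))^2)
        }
    }
    q2x <- 1 - colSums(press) / sum(tss)
    n_pc <- .select_ncomp(q2x, config$q2_gain)
    sc <- rangeScale(x)
    pc <- prcomp(sc$train, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    r2x_comp <- ev / sum(ev)
    structure(list(n_pc = n_pc, scores = pc$x, loadings = pc$rotation,
                   r2x_comp = r2x_comp,
                   r2x = sum(r2x_comp[seq_len(n_pc)]), q2x = q2x),
              class = "PcaModel")
}

#' @export
print.PcaModel <- function(x, ...) {
    cat(sprintf("PCA model: %d component(s), R2X = %.3f\n", x$n_pc, x$r2x))
    invisible(x)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic on mid-ranks with a chi-square p-value on k - 1
#' degrees of freedom (via [stats::kruskal.test()]). All-identical values
#' give H = 0, p = 1.
#'
#' @param values numeric vector
#' @param groups group label per value (at least 2 groups)
#' @return list with `H` and `p`
#' @export
kruskalWallis <- function(values, groups) {
    keep <- !is.na(values)
    values <- values[keep]; groups <- as.factor(as.character(groups[keep]))
    if (nlevels(groups) < 2L || length(values) < 2L)
        .input_error("Kruskal-Wallis needs >= 2 groups and >= 2 observations")
    if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
    kt <- kruskal.test(values, groups)
    list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Select discriminating metabolites
#'
#' A metabolite is selected when its Kruskal-Wallis p-value is below
#' `alpha` and, for at least one class, the bootstrap confidence interval of
#' its class-specific regression coefficient excludes 0 while its
#' class-specific VIP point estimate exceeds `vip_cut` (strictly). With
#' `beta_criterion = "point"` the coefficient point estimate being nonzero
#' replaces the CI criterion.
#'
#' @param kw data.frame with columns `analyte`, `H`, `p` (one row per
#'   metabolite, same variable set as the model)
#' @param boot bootstrap intervals from [bootstrapPlsda()]
#' @param model the fitted `PlsdaModel` (VIP and coefficient point
#'   estimates)
#' @param config a [qcConfig()]
#' @return data.frame: `analyte`, `H`, `p`, `p_adj`, per-class
#'   `beta_lo/beta_hi/vip` columns, `classes` (comma-joined discriminating
#'   classes) and `selected`
#' @export
selectVariables <- function(kw, boot, model, config = qcConfig()) {
    stopifnot(all(kw$analyte == rownames(model$vip)))
    p_adj <- p.adjust(kw$p, method = config$p_adjust)
    classes <- model$classes
    per_class_hit <- matrix(FALSE, nrow(kw), length(classes),
                            dimnames = list(kw$analyte, classes))
    out <- data.frame(analyte = kw$analyte, H = kw$H, p = kw$p,
                      p_adj = p_adj)
    for (k in classes) {
        beta_ok <- if (config$beta_criterion == "ci")
            boot$beta_lo[, k] > 0 | boot$beta_hi[, k] < 0
        else model$coefficients[, k] != 0
        vip_ok <- model$vip[, k] > config$vip_cut
        per_class_hit[, k] <- beta_ok & vip_ok
        out[[paste0("beta_lo_", k)]] <- boot$beta_lo[, k]
        out[[paste0("beta_hi_", k)]] <- boot$beta_hi[, k]
        out[[paste0("vip_", k)]] <- model$vip[, k]
    }
    out$classes <- apply(per_class_hit, 1, function(h)
        paste(classes[h], collapse = ","))
    out$selected <- p_adj < config$alpha & rowSums(per_class_hit) > 0
    rownames(out) <- NULL
    out
}

#' Run the complete statistics pipeline
#'
#' Enforced order: S/N filter, LOESS drift correction, QC acceptance,
#' imputation, then (with QC injections removed) PCA, PLS-DA with
#' stratified double cross-validation, bootstrap confidence intervals,
#' Kruskal-Wallis tests and variable selection.
#'
#' @param mx an [MrmExperiment-class]
#' @param config a [qcConfig()]
#' @param seed RNG seed driving folds and the bootstrap
#' @return list with `experiment`, `correction`, `qc_report`, `pca`,
#'   `plsda`, `bootstrap`, `kw` and `selection`
#' @export
runQcPipeline <- function(mx, config = qcConfig(), seed = 1) {
    mx <- filterSn(mx, config)
    lc <- loessCorrect(mx, config)
    qa <- qcAccept(lc$experiment, config)
    mx2 <- imputeMissing(qa$experiment)
    is_sample <- sampleType(mx2) == "sample"
    x <- t(assay(mx2, "area")[, is_sample, drop = FALSE])
    labels <- sampleClass(mx2)[is_sample]
    pca <- fitPca(x, config, seed = seed)
    model <- fitPlsdaCv(x, labels, config, seed = seed)
    boot <- bootstrapPlsda(x, labels, model, config, seed = seed)
    kw <- do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
        res <- kruskalWallis(x[, j], labels)
        data.frame(analyte = colnames(x)[j], H = res$H, p = res$p)
    }))
    selection <- selectVariables(kw, boot, model, config)
    list(experiment = mx2, correction = lc$correction,
         qc_report = qa$report, pca = pca, plsda = model, bootstrap = boot,
         kw = kw, selection = selection,
         relative_abundance = relativeAbundance(mx2),
         score_ellipse = if (sum(is_sample) >= 4L &&
                             ncol(model$scores) >= 2L)
             hotellingEllipse(model$scores))
}

#' Cluster-ready relative-abundance matrix
#'
#' Per metabolite, class means of the (imputed) sample areas scaled to the
#' metabolite's own range across classes, suitable for heatmap clustering.
#'
#' @param mx an imputed [MrmExperiment-class]
#' @return numeric matrix, metabolites x classes, values in [0, 1]
#' @export
relativeAbundance <- function(mx) {
    is_sample <- sampleType(mx) == "sample"
    area <- assay(mx, "area")[, is_sample, drop = FALSE]
    cls <- sampleClass(mx)[is_sample]
    means <- t(apply(area, 1, function(v) tapply(v, cls, mean,
                                                 na.rm = TRUE)))
    rng <- apply(means, 1, function(v) diff(range(v)))
    lo <- apply(means, 1, min)
    out <- (means - lo) / ifelse(rng == 0, 1, rng)
    out[rng == 0, ] <- 0.5
    out
}

#' Hotelling's T2 confidence ellipse of a 2-D score plot
#'
#' Display-only ellipse parameters for PCA/PLS-DA score plots: centre,
#' semi-axes and rotation of the (1 - alpha) Hotelling's T2 region of two
#' score columns under the F distribution.
#'
#' @param scores numeric matrix with at least two columns
#' @param level confidence level (default 0.95)
#' @param comps the two columns to use
#' @return list with `center` (length 2), `radii` (semi-axes), `angle`
#'   (radians) and `t2_crit`
#' @export
hotellingEllipse <- function(scores, level = 0.95, comps = c(1, 2)) {
    s <- scores[, comps, drop = FALSE]
    n <- nrow(s)
    if (n < 4L) .input_error("need at least 4 observations for the ellipse")
    cv <- stats::cov(s)
    t2 <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
    eg <- eigen(cv, symmetric = TRUE)
    list(center = colMeans(s),
         radii = sqrt(eg$values * t2),
         angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
         t2_crit = t2)
}

#' Read and write feature tables as long-form CSV
#'
#' Columns: `sample_id`, `injection_order`, `type`, `class`, `analyte`,
#' `area`, `sn` (empty `area`/`sn` = missing).
#'
#' @param mx an [MrmExperiment-class]
#' @param path file path
#' @export
writeFeatureTable <- function(mx, path) {
    area <- assay(mx, "area"); sn <- assay(mx, "sn")
    cd <- colData(mx)
    long <- do.call(rbind, lapply(seq_len(ncol(area)), function(j) {
        data.frame(sample_id = cd$sample_id[j],
                   injection_order = cd$injection_order[j],
                   type = cd$type[j], class = cd$class[j],
                   analyte = rownames(area), area = area[, j], sn = sn[, j])
    }))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("sample_id,injection_order,type,class,analyte,area,sn", con)
    writeLines(paste(long$sample_id, long$injection_order, long$type,
                     .format_field(long$class), long$analyte,
                     .format_field(long$area), .format_field(long$sn),
                     sep = ","), con)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @return `readFeatureTable` returns an [MrmExperiment-class]
#' @export
readFeatureTable <- function(path) {
    df <- read.csv(path, colClasses = c(sample_id = "character",
                                        injection_order = "integer",
                                        type = "character",
                                        class = "character",
                                        analyte = "character",
                                        area = "numeric", sn = "numeric"),
                   na.strings = "")
    analytes <- unique(df$analyte)
    inj <- unique(df[, c("sample_id", "injection_order", "type", "class")])
    inj <- inj[order(inj$injection_order), , drop = FALSE]
    key <- paste(df$analyte, df$injection_order)
    to_mat <- function(col) {
        m <- matrix(NA_real_, length(analytes), nrow(inj),
                    dimnames = list(analytes, inj$sample_id))
        m[cbind(match(df$analyte, analytes),
                match(df$injection_order, inj$injection_order))] <- df[[col]]
        m
    }
    MrmExperiment(to_mat("area"), to_mat("sn"),
                  injection_order = inj$injection_order, type = inj$type,
                  class = inj$class, sample_id = inj$sample_id)
}
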