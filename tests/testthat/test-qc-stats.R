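test_that("S/N filtering is strict at the threshold", {
    area <- matrix(c(10, 20, 30), 1)
    sn <- matrix(c(5.0, 5.1, 100), 1)
    mx <- make_mx(area, type = c("qc", "qc", "sample"),
                  class = c(NA, NA, "A"), sn = sn)
    out <- assay(filterSn(mx), "area")
    expect_true(is.na(out[1, 1]))     # 5.0 removed (strictly greater)
    expect_equal(unname(out[1, 2]), 20)  # 5.1 kept
    # all high: identity
    mx2 <- make_mx(area, type = c("qc", "qc", "sample"),
                   class = c(NA, NA, "A"))
    expect_equal(assay(filterSn(mx2), "area"), area,
                 ignore_attr = TRUE)
})

test_that("LOESS correction removes linear drift and spares flat series", {
    ord <- 1:20
    is_qc <- ord %% 4 == 1           # 5 QCs
    type <- ifelse(is_qc, "qc", "sample")
    cls <- ifelse(is_qc, NA, "A")
    drift <- 1 + 0.05 * ord
    area <- rbind(drifted = 1000 * drift,     # pure linear drift
                  flat = rep(800, 20))        # no drift at all
    mx <- make_mx(area, type = type, class = cls)
    res <- loessCorrect(filterSn(mx), qcConfig())
    rep_d <- res$correction[res$correction$analyte == "drifted", ]
    expect_true(rep_d$corrected)
    expect_lt(rep_d$rsd_corrected, rep_d$rsd_raw)
    # flat series: trend is constant, correction factors are 1
    flat_out <- assay(res$experiment, "area")["flat", ]
    expect_equal(unname(flat_out), rep(800, 20), tolerance = 1e-6)
})

test_that("the LOO-CV span choice matches an exhaustive grid-search oracle", {
    set.seed(33)
    ord <- 1:36
    is_qc <- ord %% 3 == 1           # 12 QCs
    type <- ifelse(is_qc, "qc", "sample")
    cls <- ifelse(is_qc, NA, "A")
    y <- 1000 * (1 + 0.3 * sin(2 * pi * ord / 36)) * exp(rnorm(36, 0, 0.03))
    mx <- make_mx(rbind(m = y), type = type, class = cls)
    res <- loessCorrect(filterSn(mx), qcConfig())
    # oracle: recompute every span's LOO error directly
    xq <- ord[is_qc]; yq <- y[is_qc]
    grid <- seq(0.3, 1, by = 0.1)
    cv <- vapply(grid, function(s) {
        mean(vapply(seq_along(xq), function(i) {
            fit <- tryCatch(suppressWarnings(
                stats::loess(yq[-i] ~ xq[-i], span = s, degree = 1,
                             control = stats::loess.control(
                                 surface = "direct"))),
                error = function(e) NULL)
            if (is.null(fit)) return(Inf)
            pr <- predict(fit, newdata = xq[i])
            if (!is.finite(pr)) Inf else (pr - yq[i])^2
        }, numeric(1)))
    }, numeric(1))
    expect_equal(res$correction$span, grid[which.min(cv)])
    expect_true(res$correction$corrected)
})

test_that("correction is skipped with too few QCs and never raises QC RSD", {
    area <- rbind(m = c(100, 110, 120, 105, 95, 100))
    mx <- make_mx(area, type = c("qc", "qc", "qc", "sample", "sample",
                                 "sample"),
                  class = c(NA, NA, NA, "A", "A", "A"))
    expect_warning(res <- loessCorrect(filterSn(mx), qcConfig()),
                   "fewer than 4 QC")
    expect_false(res$correction$corrected)
    expect_equal(assay(res$experiment, "area"), area, ignore_attr = TRUE)
    # property: for random series, corrected QC RSD <= raw QC RSD
    set.seed(8)
    ord <- 1:24; is_qc <- ord %% 4 == 1
    for (i in 1:10) {
        y <- 500 * (1 + runif(1, -0.3, 0.3) * ord / 24) *
            exp(rnorm(24, 0, 0.1))
        mx2 <- make_mx(rbind(m = y), type = ifelse(is_qc, "qc", "sample"),
                       class = ifelse(is_qc, NA, "A"))
        r <- loessCorrect(filterSn(mx2), qcConfig())
        if (r$correction$corrected)
            expect_lte(r$correction$rsd_corrected, r$correction$rsd_raw)
    }
})

test_that("QC acceptance applies the RSD and missingness thresholds", {
    area <- rbind(good = c(100, 100, 100, 50),
                  wild = c(50, 150, 100, 50),
                  holey = c(100, NA, NA, 60))
    sn <- matrix(100, 3, 4)
    sn[3, 2:3] <- 1  # the S/N filter creates the QC holes
    mx0 <- make_mx(area, type = c("qc", "qc", "qc", "sample"),
                   class = c(NA, NA, NA, "A"), sn = sn)
    mx0 <- filterSn(mx0)
    suppressWarnings(lc <- loessCorrect(mx0, qcConfig()))
    qa <- qcAccept(lc$experiment, qcConfig())
    rep_ <- qa$report
    expect_equal(rep_$qc_rsd[rep_$analyte == "good"], 0)
    expect_true(rep_$pass[rep_$analyte == "good"])
    # {50, 150}: sd/mean = 70.71..., fails
    expect_equal(rep_$qc_rsd[rep_$analyte == "wild"],
                 100 * sd(c(50, 150, 100)) / 100, tolerance = 1e-12)
    # 2 of 3 QC cells missing (66 %) fails the missing criterion
    expect_false(rep_$pass[rep_$analyte == "holey"])
    expect_equal(rownames(qa$experiment), "good")
})

test_that("QC RSD of {50, 150} is the direct sd/mean value", {
    area <- rbind(m = c(50, 150, 70))
    mx <- make_mx(area, type = c("qc", "qc", "sample"),
                  class = c(NA, NA, "A"))
    suppressWarnings(lc <- loessCorrect(filterSn(mx), qcConfig()))
    qa <- qcAccept(lc$experiment, qcConfig())
    expect_equal(qa$report$qc_rsd, 100 * sd(c(50, 150)) / 100,
                 tolerance = 1e-12)       # ~70.7 %
    expect_false(qa$report$pass)
    # 2 of 6 QCs missing = 33 % > 30 %: fails on missingness alone
    area2 <- rbind(m = c(100, 101, NA, NA, 99, 100, 55))
    mx2 <- make_mx(area2, type = c(rep("qc", 6), "sample"),
                   class = c(rep(NA, 6), "A"))
    qa2 <- qcAccept(loessCorrect(filterSn(mx2),
                                 qcConfig())$experiment, qcConfig())
    expect_false(qa2$report$pass)
    expect_gt(qa2$report$qc_missing, 30)
})

test_that("imputation distinguishes class-wise MAR from MNAR", {
    # columns: 2 QCs then classes A, A, A, B, B, B
    area <- rbind(mar = c(100, 100, 10, NA, 14, 8, 9, 10),
                  mnar = c(100, 100, 12, 11, 13, NA, NA, NA),
                  full = c(100, 100, 1, 2, 3, 4, 5, 6))
    type <- c("qc", "qc", rep("sample", 6))
    cls <- c(NA, NA, rep(c("A", "B"), each = 3))
    mx <- make_mx(area, type = type, class = cls)
    # walk the enforced order
    suppressWarnings(mx <- loessCorrect(filterSn(mx),
                                        qcConfig())$experiment)
    mx <- qcAccept(mx, qcConfig(rsd_max = 1000))$experiment
    out <- imputeMissing(mx)
    a <- assay(out, "area")
    expect_equal(unname(a["mar", 4]), 12)    # class mean of {10, 14}
    expect_equal(a["mnar", 6:8], rep(11 / 2, 3),
                 ignore_attr = TRUE)         # half of global min 11
    expect_equal(a["full", ], area[3, ], ignore_attr = TRUE)
    log <- metadata(out)$imputation_log
    expect_setequal(log$rule[log$analyte == "mnar"], "MNAR_half_min")
    expect_setequal(log$rule[log$analyte == "mar"], "MAR_class_mean")
})

test_that("a metabolite missing everywhere is dropped with a warning", {
    area <- rbind(gone = c(100, 100, NA, NA),
                  ok = c(100, 100, 5, 6))
    mx <- make_mx(area, type = c("qc", "qc", "sample", "sample"),
                  class = c(NA, NA, "A", "B"))
    suppressWarnings(mx <- loessCorrect(filterSn(mx),
                                        qcConfig())$experiment)
    mx <- qcAccept(mx, qcConfig(qc_missing_max = 101,
                                rsd_max = 1000))$experiment
    expect_warning(out <- imputeMissing(mx), "dropped")
    expect_equal(rownames(out), "ok")
})

test_that("the pipeline order is enforced", {
    mx <- make_mx(matrix(1:8, 2), type = c("qc", "qc", "sample", "sample"),
                  class = c(NA, NA, "A", "B"))
    mx <- filterSn(mx)
    suppressWarnings(mx <- loessCorrect(mx, qcConfig())$experiment)
    mx <- qcAccept(mx, qcConfig(rsd_max = 1000))$experiment
    mx <- imputeMissing(mx)
    expect_error(filterSn(mx), class = "fiamrm_input_error")
    expect_error(loessCorrect(mx), class = "fiamrm_input_error")
    expect_error(qcAccept(mx), class = "fiamrm_input_error")
})

test_that("range scaling is leakage-free and flags constants", {
    tr <- cbind(a = c(0, 5, 10), b = c(3, 3, 3))
    te <- cbind(a = 12, b = 7)
    sc <- rangeScale(tr, te)
    expect_equal(sc$train[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
    expect_equal(sc$test[1, "a"], 1.2, ignore_attr = TRUE)  # no clipping
    expect_true(sc$limits$constant[2])
    expect_equal(sc$train[, "b"], rep(0, 3), ignore_attr = TRUE)
    expect_equal(sc$test[1, "b"], 0, ignore_attr = TRUE)
})

test_that("PCA explains planted structure", {
    set.seed(21)
    # rank-1 data plus tiny noise: first component takes nearly everything
    z <- rnorm(30)
    x1 <- outer(z, runif(8, 1, 2)) + matrix(rnorm(240, 0, 0.01), 30, 8)
    m1 <- fitPca(x1, qcConfig(), seed = 1)
    expect_gt(m1$r2x_comp[1], 0.99)
    expect_equal(sum(m1$r2x_comp), 1, tolerance = 1e-8)
    # three well-separated clusters: scores separate by group
    centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
    g <- rep(1:3, each = 10)
    x3 <- centers[g, ] %*% matrix(runif(2 * 6, 0.5, 1.5), 2, 6) +
        matrix(rnorm(180, 0, 0.3), 30, 6)
    m3 <- fitPca(x3, qcConfig(), seed = 1)
    sc <- m3$scores[, 1:2, drop = FALSE]
    within <- mean(vapply(1:3, function(k)
        mean(dist(sc[g == k, ])), numeric(1)))
    between <- mean(dist(rowsum(sc, g) / 10))
    expect_gt(between, within)
})

test_that("PLS-DA separates separable classes and fails permuted labels", {
    set.seed(61)
    n <- 20
    x <- matrix(rnorm(n * 10), n, 10)
    x[1:10, 1:3] <- x[1:10, 1:3] + 8
    labels <- rep(c("A", "B"), each = 10)
    m <- fitPlsdaCv(x, labels, qcConfig(), seed = 1)
    expect_equal(m$accuracy, 1)
    expect_gt(m$q2y, 0.9)
    expect_lte(m$q2y, m$r2y)
    expect_lte(m$r2y, 1)
    # VIP normalization: mean squared VIP over variables is 1 per class
    expect_equal(unname(colMeans(m$vip^2)), c(1, 1), tolerance = 1e-8)
    # permuted labels carry no information
    q2p <- vapply(1:5, function(i) {
        perm <- fiamrm:::.with_seed(100 + i, sample(labels))
        fitPlsdaCv(x, perm, qcConfig(), seed = i)$q2y
    }, numeric(1))
    expect_lte(mean(q2p), 0)
    # stratification contract
    expect_error(fitPlsdaCv(x[1:6, ], labels[c(1:3, 11:13)], qcConfig()),
                 class = "fiamrm_input_error")
})

test_that("the gain rule finds planted dimensionality", {
    set.seed(62)
    z <- rnorm(30)
    x <- outer(z, rnorm(20)) + matrix(rnorm(600, 0, 0.1), 30, 20)
    m <- fitPlsdaCv(x, ifelse(z > 0, "A", "B"), qcConfig(), seed = 2)
    expect_equal(m$n_lv, 1L)
})

test_that("NIPALS agrees with an independent PLS-DA implementation", {
    skip_if_not_installed("mixOmics")
    set.seed(63)
    x <- matrix(rnorm(30 * 8), 30, 8)
    x[1:15, 1:2] <- x[1:15, 1:2] + 3
    labels <- rep(c("A", "B"), each = 15)
    fit <- fiamrm:::.nipals_pls(x, fiamrm:::.one_hot(labels), 2)
    ref <- mixOmics::plsda(x, factor(labels), ncomp = 2, scale = FALSE)
    # scores of the first latent variable agree up to sign
    expect_gt(abs(cor(fit$scores[, 1], ref$variates$X[, 1])), 0.999)
})

test_that("bootstrap intervals are ordered, seeded and detect effects", {
    set.seed(64)
    n <- 24
    x <- cbind(strong = c(rnorm(8, 10), rnorm(8, 0), rnorm(8, 0)),
               matrix(rnorm(n * 9), n, 9))
    colnames(x) <- c("strong", paste0("noise", 1:9))
    labels <- rep(c("A", "B", "C"), each = 8)
    cfg <- qcConfig(n_boot = 50)
    m <- fitPlsdaCv(x, labels, cfg, seed = 3)
    b1 <- bootstrapPlsda(x, labels, m, cfg, seed = 9)
    b2 <- bootstrapPlsda(x, labels, m, cfg, seed = 9)
    expect_identical(b1, b2)                       # determinism
    expect_true(all(b1$beta_lo <= b1$beta_hi + 1e-12))
    expect_true(all(b1$vip_lo <= b1$vip_hi + 1e-12))
    expect_true(all(b1$vip_lo >= 0))
    # the planted discriminator has a VIP interval above 1 for its class
    expect_gt(b1$vip_lo["strong", "A"], 1)
    # noise variables reach below-1 VIP territory
    expect_true(any(b1$vip_lo[-1, "A"] < 1))
})

test_that("relative abundance and score ellipse are well-formed exports", {
    area <- rbind(up = c(100, 100, 9, 10, 11, 2, 3, 4),
                  flat = c(100, 100, 5, 5, 5, 5, 5, 5))
    mx <- make_mx(area, type = c("qc", "qc", rep("sample", 6)),
                  class = c(NA, NA, rep(c("A", "B"), each = 3)))
    ra <- relativeAbundance(mx)
    expect_equal(unname(ra["up", ]), c(1, 0))     # A mean 10 > B mean 3
    expect_equal(unname(ra["flat", ]), c(0.5, 0.5))
    set.seed(77)
    ell <- hotellingEllipse(matrix(rnorm(40), 20, 2))
    expect_length(ell$radii, 2L)
    expect_true(all(ell$radii > 0))
    expect_error(hotellingEllipse(matrix(0, 3, 2)),
                 class = "fiamrm_input_error")
})

test_that("Kruskal-Wallis H matches the hand rank-sum value", {
    res <- kruskalWallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                         rep(c("a", "b", "c"), each = 3))
    # ranks 1..9, no ties: H = 12/(9*10) * (6^2+15^2+24^2)/3 - 3*10 = 7.2
    expect_equal(res$H, 7.2, tolerance = 1e-12)
    expect_equal(res$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
    expect_equal(kruskalWallis(rep(5, 9),
                               rep(c("a", "b", "c"), each = 3)),
                 list(H = 0, p = 1))
    expect_error(kruskalWallis(1:5, rep("a", 5)),
                 class = "fiamrm_input_error")
})

test_that("variable selection is the strict three-way conjunction", {
    vip <- matrix(c(1.8, 0.4, 1.0, 0.5, 1.7, 0.9), 3, 2,
                  dimnames = list(c("m1", "m2", "m3"), c("A", "B")))
    model <- structure(list(classes = c("A", "B"), vip = vip,
                            coefficients = vip * 0.1), class = "PlsdaModel")
    boot <- list(beta_lo = matrix(0.2, 3, 2, dimnames = dimnames(vip)),
                 beta_hi = matrix(0.5, 3, 2, dimnames = dimnames(vip)))
    kw <- data.frame(analyte = c("m1", "m2", "m3"),
                     H = c(9, 2, 9), p = c(0.001, 0.2, 0.001))
    out <- selectVariables(kw, boot, model, qcConfig())
    expect_true(out$selected[out$analyte == "m1"])     # all criteria met
    expect_false(out$selected[out$analyte == "m2"])    # p too large
    expect_false(out$selected[out$analyte == "m3"])    # VIP == 1 exactly
    expect_equal(out$classes[out$analyte == "m1"], "A")
    # beta CI spanning zero blocks selection under the CI criterion
    boot0 <- list(beta_lo = matrix(-0.1, 3, 2, dimnames = dimnames(vip)),
                  beta_hi = matrix(0.5, 3, 2, dimnames = dimnames(vip)))
    out0 <- selectVariables(kw, boot0, model, qcConfig())
    expect_false(any(out0$selected))
    # point-estimate mode ignores the interval
    outp <- selectVariables(kw, boot0, model,
                            qcConfig(beta_criterion = "point"))
    expect_true(outp$selected[outp$analyte == "m1"])
})
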