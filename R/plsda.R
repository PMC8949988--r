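## Multiclass PLS-DA: NIPALS PLS2 on a one-hot response, with class-specific
## regression coefficients and VIP scores, stratified double cross-validation
## for latent-variable selection and Q2Y estimation, and bootstrap percentile
## confidence intervals.

.one_hot <- function(labels, classes = sort(unique(labels))) {
    Y <- matrix(0, length(labels), length(classes),
                dimnames = list(NULL, classes))
    Y[cbind(seq_along(labels), match(labels, classes))] <- 1
    Y
}

# NIPALS PLS2 on column-centered X and Y. Returns weights W, scores T,
# X-loadings P, Y-loadings Q plus fit statistics. Components whose X weight
# vector degenerates to zero norm are dropped.
.nipals_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500L) {
    n <- nrow(X); p <- ncol(X); q <- ncol(Y)
    x_mean <- colMeans(X); y_mean <- colMeans(Y)
    Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
    ssx_tot <- sum(Xc^2); ssy_tot <- sum(Yc^2)
    W <- P <- matrix(0, p, 0); Q <- matrix(0, q, 0); Tm <- matrix(0, n, 0)
    Xa <- Xc; Ya <- Yc
    ssx_comp <- ssy_comp <- numeric(0)
    for (a in seq_len(ncomp)) {
        u <- Ya[, which.max(colSums(Ya^2))]
        t_old <- rep(Inf, n)
        w <- t <- NULL
        for (it in seq_len(maxit)) {
            w <- drop(crossprod(Xa, u))
            nw <- sqrt(sum(w^2))
            if (nw < .Machine$double.eps^0.5) return(NULL)
            w <- w / nw
            t <- drop(Xa %*% w)
            qv <- drop(crossprod(Ya, t)) / sum(t^2)
            u <- drop(Ya %*% qv) / sum(qv^2)
            if (sum((t - t_old)^2) < tol * sum(t^2)) break
            t_old <- t
        }
        if (sum(t^2) < .Machine$double.eps) break
        pv <- drop(crossprod(Xa, t)) / sum(t^2)
        qv <- drop(crossprod(Ya, t)) / sum(t^2)
        Xa <- Xa - tcrossprod(t, pv)
        Ya <- Ya - tcrossprod(t, qv)
        W <- cbind(W, w); P <- cbind(P, pv); Q <- cbind(Q, qv)
        Tm <- cbind(Tm, t)
        ssx_comp <- c(ssx_comp, sum(tcrossprod(t, pv)^2))
        ssy_comp <- c(ssy_comp, sum(tcrossprod(t, qv)^2))
    }
    if (!ncol(W)) return(NULL)
    list(W = W, P = P, Q = Q, scores = Tm, x_mean = x_mean, y_mean = y_mean,
         ncomp = ncol(W),
         r2x_comp = ssx_comp / ssx_tot, r2y_comp = ssy_comp / ssy_tot,
         ssy_tot = ssy_tot)
}

# Regression coefficients (p x q) using the first `a` components.
.pls_coef <- function(fit, a = fit$ncomp) {
    W <- fit$W[, seq_len(a), drop = FALSE]
    P <- fit$P[, seq_len(a), drop = FALSE]
    Q <- fit$Q[, seq_len(a), drop = FALSE]
    W %*% solve(crossprod(P, W), t(Q))
}

.pls_predict <- function(fit, Xnew, a = fit$ncomp) {
    B <- .pls_coef(fit, a)
    sweep(sweep(Xnew, 2, fit$x_mean) %*% B, 2, fit$y_mean, "+")
}

# Class-specific VIP (p x q): for response column k, component a explains
# SS_{a,k} = q_{k,a}^2 t_a' t_a of that column, and
# VIP_{j,k}^2 = p * sum_a SS_{a,k} w_{ja}^2 / sum_a SS_{a,k}.
# Weight vectors have unit norm, so mean_j VIP_{j,k}^2 = 1 for every class.
.pls_vip <- function(fit) {
    p <- nrow(fit$W); q <- nrow(fit$Q)
    tt <- colSums(fit$scores^2)
    vip <- matrix(0, p, q, dimnames = list(rownames(fit$W), rownames(fit$Q)))
    for (k in seq_len(q)) {
        ss <- fit$Q[k, ]^2 * tt
        if (sum(ss) <= 0) { vip[, k] <- 0; next }
        vip[, k] <- sqrt(p * drop(fit$W^2 %*% ss) / sum(ss))
    }
    vip
}

# Cross-validated Q2Y for 1..ncomp_max components: stratified folds, range
# scaling fitted on each training split (leakage-free), PRESS pooled over
# folds against the training-mean baseline.
.cv_q2y <- function(x, labels, ncomp_max, folds, seed) {
    classes <- sort(unique(labels))
    Y <- .one_hot(labels, classes)
    fold_of <- .stratified_folds(labels, folds, seed = seed)
    press <- matrix(0, folds, ncomp_max)
    tss <- numeric(folds)
    for (f in seq_len(folds)) {
        tr <- fold_of != f; te <- !tr
        sc <- rangeScale(x[tr, , drop = FALSE], x[te, , drop = FALSE])
        fit <- .nipals_pls(sc$train, Y[tr, , drop = FALSE], ncomp_max)
        if (is.null(fit)) return(rep(NA_real_, ncomp_max))
        tss[f] <- sum(sweep(Y[te, , drop = FALSE], 2,
                            colMeans(Y[tr, , drop = FALSE]))^2)
        for (a in seq_len(ncomp_max)) {
            aa <- min(a, fit$ncomp)
            pred <- .pls_predict(fit, sc$test, aa)
            press[f, a] <- sum((Y[te, , drop = FALSE] - pred)^2)
        }
    }
    1 - colSums(press) / sum(tss)
}

# Latent-variable count by the gain rule: add components while the
# cross-validated Q2Y improves by at least `gain`; stop at the first
# component whose successor adds less.
.select_ncomp <- function(q2, gain) {
    if (all(is.na(q2))) return(1L)
    a <- 1L
    while (a < length(q2) && !is.na(q2[a + 1L]) &&
           (q2[a + 1L] - q2[a]) >= gain) a <- a + 1L
    a
}

#' Fit a multiclass PLS-DA model with stratified double cross-validation
#'
#' The response is the one-hot class-membership matrix; class calls are the
#' argmax of the predicted columns. An outer stratified k-fold estimates the
#' goodness of prediction Q2Y (and classification accuracy), with the
#' latent-variable count selected inside each training split by an inner
#' stratified k-fold under the gain rule: stop adding latent variables when
#' the inner Q2Y gain drops below `q2_gain`. Range scaling is refitted on
#' every training split so no test information leaks. The final model is
#' refit on all samples with the latent-variable count selected by the
#' inner rule on the full data.
#'
#' @param x numeric matrix, samples x metabolites (imputed; raw scale -
#'   range scaling happens inside the pipeline)
#' @param labels class label per row; every class needs at least
#'   `cv_folds` members
#' @param config a [qcConfig()] (uses `cv_folds` and `q2_gain`)
#' @param seed RNG seed for the fold assignments
#' @param ncomp_max largest latent-variable count examined
#' @return object of class `PlsdaModel`: `n_lv`, `classes`, `scores`,
#'   `loadings`, `weights`, `coefficients` (variables x classes), `vip`
#'   (variables x classes), `r2x`, `r2x_comp`, `r2y`, `q2y`, `accuracy`,
#'   and the final `fit`
#' @export
fitPlsdaCv <- function(x, labels, config = qcConfig(), seed = 1,
                       ncomp_max = NULL) {
    labels <- as.character(labels)
    classes <- sort(unique(labels))
    if (length(classes) < 2L)
        .input_error("PLS-DA needs at least two classes")
    if (any(table(labels) < config$cv_folds))
        .input_error("every class needs at least cv_folds members for stratification")
    n <- nrow(x)
    if (is.null(ncomp_max))
        ncomp_max <- max(1L, min(10L, n - ceiling(n / config$cv_folds) - 1L,
                                 ncol(x)))
    Y <- .one_hot(labels, classes)
    fold_of <- .stratified_folds(labels, config$cv_folds, seed = seed)
    press <- 0; tss <- 0; correct <- 0L
    for (f in seq_len(config$cv_folds)) {
        tr <- fold_of != f; te <- !tr
        q2_inner <- .cv_q2y(x[tr, , drop = FALSE], labels[tr], ncomp_max,
                            config$cv_folds, seed = seed + f)
        a <- .select_ncomp(q2_inner, config$q2_gain)
        sc <- rangeScale(x[tr, , drop = FALSE], x[te, , drop = FALSE])
        fit <- .nipals_pls(sc$train, Y[tr, , drop = FALSE], a)
        pred <- .pls_predict(fit, sc$test, min(a, fit$ncomp))
        press <- press + sum((Y[te, , drop = FALSE] - pred)^2)
        tss <- tss + sum(sweep(Y[te, , drop = FALSE], 2,
                               colMeans(Y[tr, , drop = FALSE]))^2)
        correct <- correct +
            sum(classes[max.col(pred)] == labels[te])
    }
    q2y <- 1 - press / tss
    q2_full <- .cv_q2y(x, labels, ncomp_max, config$cv_folds, seed = seed)
    n_lv <- .select_ncomp(q2_full, config$q2_gain)
    sc <- rangeScale(x)
    fit <- .nipals_pls(sc$train, Y, n_lv)
    structure(list(
        n_lv = fit$ncomp, classes = classes,
        scores = fit$scores, loadings = fit$P, weights = fit$W,
        coefficients = {
            B <- .pls_coef(fit); dimnames(B) <- list(colnames(x), classes); B
        },
        vip = {
            V <- .pls_vip(fit); dimnames(V) <- list(colnames(x), classes); V
        },
        r2x = sum(fit$r2x_comp), r2x_comp = fit$r2x_comp,
        r2y = sum(fit$r2y_comp), q2y = q2y, q2y_inner = q2_full,
        accuracy = correct / n,
        scaling = sc$limits, fit = fit),
        class = "PlsdaModel")
}

#' @export
print.PlsdaModel <- function(x, ...) {
    cat(sprintf("PLS-DA model: %d classes, %d latent variable(s)\n",
                length(x$classes), x$n_lv))
    cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2Y = %.3f  CV accuracy = %.3f\n",
                x$r2x, x$r2y, x$q2y, x$accuracy))
    invisible(x)
}

#' Bootstrap percentile confidence intervals for PLS-DA parameters
#'
#' Draws `n_boot` class-stratified resamples with replacement, refits the
#' range-scaling + NIPALS pipeline with the model's latent-variable count on
#' each, and returns 2.5/97.5 percentile confidence intervals for every
#' class-specific regression coefficient and VIP score. Stratification keeps
#' every class present in every resample; a resample on which the fit
#' degenerates (e.g. all-constant predictors) is redrawn.
#'
#' @param x,labels as in [fitPlsdaCv()]
#' @param model a fitted `PlsdaModel`
#' @param config a [qcConfig()] (uses `n_boot`)
#' @param seed RNG seed; identical seeds give identical intervals
#' @return list with arrays `beta_lo`, `beta_hi`, `vip_lo`, `vip_hi`
#'   (variables x classes) and the bootstrap draw count `n_boot`
#' @export
bootstrapPlsda <- function(x, labels, model, config = qcConfig(), seed = 1) {
    labels <- as.character(labels)
    classes <- model$classes
    Y <- .one_hot(labels, classes)
    idx_by_class <- split(seq_along(labels), labels)
    p <- ncol(x); q <- length(classes)
    beta <- array(NA_real_, c(p, q, config$n_boot))
    vip <- array(NA_real_, c(p, q, config$n_boot))
    .with_seed(seed, {
        b <- 1L
        guard <- 0L
        while (b <= config$n_boot) {
            idx <- unlist(lapply(idx_by_class, function(ii)
                sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
            sc <- rangeScale(x[idx, , drop = FALSE])
            fit <- .nipals_pls(sc$train, Y[idx, , drop = FALSE], model$n_lv)
            if (is.null(fit)) {
                guard <- guard + 1L
                if (guard > 50L)
                    .input_error("bootstrap resamples repeatedly degenerate")
                next
            }
            beta[, , b] <- .pls_coef(fit)
            vip[, , b] <- .pls_vip(fit)
            b <- b + 1L; guard <- 0L
        }
    })
    pct <- function(a, pr) apply(a, c(1, 2), quantile, probs = pr,
                                 na.rm = TRUE)
    dn <- list(colnames(x), classes)
    out <- list(beta_lo = pct(beta, 0.025), beta_hi = pct(beta, 0.975),
                vip_lo = pct(vip, 0.025), vip_hi = pct(vip, 0.975),
                n_boot = config$n_boot)
    out <- lapply(out, function(m) {
        if (is.matrix(m)) dimnames(m) <- dn
        m
    })
    out
}
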