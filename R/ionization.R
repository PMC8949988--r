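## pKa-based species classification and electrospray polarity allocation.
##
## The taxonomy works on per-group pKa values: the strongest group governs,
## i.e. a = min over acidic-group pKa values, b = max over basic-group pKa
## values. An acidic group is "strong" when a < acid_cut (default 6.5), a
## basic group when b > base_cut (default 8.5); boundary equality counts as
## weak. The (a, b) plane is partitioned completely:
##
##   no groups                          -> unclassified
##   strong acid, no/weak/any basic<cut -> acid      (e.g. ATP, UTP)
##   strong base, no/weak acid          -> base      (e.g. ammonia, kanamycin)
##   strong acid AND strong base        -> amphoteric (amino acids)
##   everything else (only weak groups) -> neutral   (tricine, pyridoxine)

#' Classification thresholds for ionization behaviour
#'
#' @param acid_cut acidic-group pKa below which a proton donor counts as
#'   strong (default 6.5)
#' @param base_cut basic-group pKa above which a proton acceptor counts as
#'   strong (default 8.5)
#' @return list of class `ClassifierThresholds`
#' @export
classifierThresholds <- function(acid_cut = 6.5, base_cut = 8.5) {
    if (!is.finite(acid_cut) || !is.finite(base_cut) || acid_cut >= base_cut)
        .input_error("need finite thresholds with acid_cut < base_cut")
    structure(list(acid_cut = acid_cut, base_cut = base_cut),
              class = "ClassifierThresholds")
}

#' Classify a metabolite's ionization species from per-group pKa values
#'
#' @param pka a [pkaSet()] or `NULL` (no pKa information)
#' @param thresholds a [classifierThresholds()]
#' @return one of `"acid"`, `"base"`, `"amphoteric"`, `"neutral"`,
#'   `"unclassified"`
#' @examples
#' classifySpecies(pkaSet(acidic = c(1.1, 3.8), basic = 5.0))  # acid (ATP-like)
#' classifySpecies(pkaSet(acidic = 2.3, basic = 9.7))          # amphoteric
#' classifySpecies(pkaSet(acidic = 7.2))                       # neutral
#' @export
classifySpecies <- function(pka, thresholds = classifierThresholds()) {
    if (is.null(pka)) return("unclassified")
    stopifnot(inherits(pka, "PkaSet"))
    if (!all(is.finite(c(pka$acidic, pka$basic))))
        .input_error("non-finite pKa value")
    a <- if (length(pka$acidic)) min(pka$acidic) else NA_real_
    b <- if (length(pka$basic)) max(pka$basic) else NA_real_
    strong_a <- !is.na(a) && a < thresholds$acid_cut
    strong_b <- !is.na(b) && b > thresholds$base_cut
    if (strong_a && strong_b) "amphoteric"
    else if (strong_a) "acid"
    else if (strong_b) "base"
    else "neutral"
}

#' Allocate electrospray ionization mode(s) from a species class
#'
#' Acids are deprotonated and go to negative mode, bases protonated to
#' positive mode. Amphoteric molecules (and neutral molecules carrying both
#' a weak acidic and a weak basic group) are allocated to both modes with the
#' final choice deferred to transition selection, where isobaric convolutions
#' can still be avoided. Weak-single-group neutrals keep the polarity their
#' only group supports. Unclassified metabolites (no pKa) cannot be allocated
#' and are excluded from the method.
#'
#' @param cls a class string from [classifySpecies()]
#' @param pka the [pkaSet()] behind the class (needed to split the neutral
#'   cases); may be `NULL` for non-neutral classes
#' @return list with `modes` (character subset of positive/negative) and
#'   `deferred` (logical)
#' @export
allocateMode <- function(cls, pka = NULL) {
    switch(cls,
        acid = list(modes = "negative", deferred = FALSE),
        base = list(modes = "positive", deferred = FALSE),
        amphoteric = list(modes = c("positive", "negative"), deferred = TRUE),
        neutral = {
            if (is.null(pka))
                .input_error("neutral allocation needs the pKa set")
            has_a <- length(pka$acidic) > 0L
            has_b <- length(pka$basic) > 0L
            if (has_a && has_b)
                list(modes = c("positive", "negative"), deferred = TRUE)
            else if (has_a) list(modes = "negative", deferred = FALSE)
            else list(modes = "positive", deferred = FALSE)
        },
        unclassified = .input_error(
            "metabolite dropped: no pKa information, no ionization mode"),
        .input_error(sprintf("unknown species class '%s'", cls)))
}

#' Validate predicted against experimental pKa values
#'
#' Ordinary least-squares regression of experimental on predicted values
#' plus per-compound deviations (predicted minus experimental, pKa units)
#' and per-category maximum absolute deviation. With fewer than 3 pairs the
#' regression is omitted and only deviations are returned.
#'
#' @param pairs data.frame with columns `predicted`, `experimental` and
#'   `category` (each in acid/base/amphoteric)
#' @return list with `slope`, `intercept`, `r2` (NA when regression
#'   omitted), `deviations` (per-pair delta) and `by_category` (max |delta|
#'   per category)
#' @export
validatePka <- function(pairs) {
    stopifnot(all(c("predicted", "experimental", "category") %in%
                  colnames(pairs)))
    if (!all(pairs$category %in% c("acid", "base", "amphoteric")))
        .input_error("categories must be acid, base or amphoteric")
    delta <- pairs$predicted - pairs$experimental
    by_cat <- tapply(abs(delta), pairs$category, max)
    slope <- intercept <- r2 <- NA_real_
    if (nrow(pairs) >= 3L) {
        fit <- lm(experimental ~ predicted, data = pairs)
        slope <- unname(coef(fit)[2])
        intercept <- unname(coef(fit)[1])
        ss_res <- sum(fit$residuals^2)
        ss_tot <- sum((pairs$experimental - mean(pairs$experimental))^2)
        r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    }
    list(slope = slope, intercept = intercept, r2 = r2,
         deviations = delta,
         by_category = by_cat[!is.na(by_cat)])
}
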