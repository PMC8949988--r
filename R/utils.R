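## Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = genv)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    expr
}

# Stratified fold assignment: within each class, members are dealt to folds
# in a rotating fashion after a seeded shuffle, so every fold holds roughly
# n_k / folds members of class k.
.stratified_folds <- function(labels, folds, seed = NULL) {
    out <- integer(length(labels))
    run <- function() {
        for (k in unique(labels)) {
            idx <- which(labels == k)
            idx <- sample(idx)
            out[idx] <<- rep_len(seq_len(folds), length(idx))
        }
        out
    }
    if (!is.null(seed)) .with_seed(seed, run()) else run()
}
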