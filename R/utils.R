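#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return The geometric mean of `x`.
#' @keywords internal
geomean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

#' Derive a deterministic sub-seed from a global seed
#'
#' Derived streams keep every stage reproducible from one integer without
#' callers having to book-keep seeds. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param offset integer stream offset (one per library/stage).
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table is used via explicit calls; mark the package data.table-aware
.datatable.aware <- TRUE
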