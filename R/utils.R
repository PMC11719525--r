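#' @importFrom stats median quantile rbinom rmultinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strip trailing ".version" suffixes from feature identifiers
#'
#' GENCODE metadata files and GTF attribute strings disagree on whether
#' gene/transcript identifiers carry a version suffix (`ENST00000123456.7`
#' vs `ENST00000123456`); comparisons are always made on the unversioned id.
#'
#' @param x character vector of identifiers.
#' @return character vector with a final `.<digits>` removed.
#' @export
strip_version <- function(x) sub("\\.[0-9]+$", "", x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a labelled RNG seed from a master seed
#'
#' Each synthetic artifact draws from its own stream, derived from the master
#' seed and a fixed label, so adding artifacts never perturbs existing ones.
#' Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}
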