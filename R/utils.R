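#' Derive a stage-specific seed from a run seed
#'
#' Mixes the master seed with a stage name so that pipeline stages consume
#' independent, reproducible random streams and can be rerun in isolation.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name, e.g. \code{"library"} or
#'   \code{"pvalue"}.
#' @return An integer seed.
#' @examples
#' stageSeed(1, "library")
#' @export
stageSeed <- function(seed, stage) {
    stopifnot(length(seed) == 1, is.finite(seed), is.character(stage))
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
    as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

#' Amino-acid composition of a sequence window
#'
#' Percentage of each residue within a 1-based closed position range of a
#' protein sequence. Used, for example, to quantify the arginine/alanine
#' enrichment of low-complexity N-terminal domains.
#'
#' @param sequence Single amino-acid string (or \code{AAString}).
#' @param from,to 1-based closed window bounds; \code{to} is clipped to the
#'   sequence length.
#' @return Named numeric vector of percentages summing to 100.
#' @examples
#' residueComposition("RRAAG", 1, 5)
#' @export
residueComposition <- function(sequence, from = 1L, to = NULL) {
    s <- as.character(sequence)
    stopifnot(length(s) == 1, nzchar(s))
    n <- nchar(s)
    if (is.null(to)) to <- n
    to <- min(to, n)
    stopifnot(from >= 1, from <= to)
    aa <- strsplit(substr(s, from, to), "")[[1]]
    100 * table(factor(aa, levels = sort(unique(aa)))) / length(aa)
}

## internal: largest-remainder apportionment of `total` over weights `w`
.apportion <- function(w, total) {
    stopifnot(all(w >= 0), sum(w) > 0, total >= 0)
    q <- w / sum(w) * total
    base <- floor(q)
    short <- total - sum(base)
    if (short > 0) {
        extra <- order(q - base, decreasing = TRUE)[seq_len(short)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}
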