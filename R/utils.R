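#' Truncate a number toward zero at a fixed number of decimals
#'
#' Reported percentages and ratios in EST mining tables are conventionally
#' printed truncated, not rounded (e.g. 56.289 prints as 56.28). `trunc_dp()`
#' applies that convention; full-precision values are always kept alongside.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return `x` truncated toward zero at `digits` decimals.
#' @export
#' @examples
#' trunc_dp(56.289, 2)  # 56.28
trunc_dp <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname revcomp
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname revcomp
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# split a single sequence into a character vector of residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' G+C fraction of a sequence
#'
#' N residues are excluded from both numerator and denominator.
#'
#' @param x character vector of sequences.
#' @return numeric vector of G+C fractions in `[0, 1]` (NaN for all-N input).
#' @export
gc_fraction <- function(x) {
  vapply(x, function(s) {
    ch <- seq_chars(toupper(s))
    ch <- ch[ch != "N"]
    if (!length(ch)) return(NaN)
    mean(ch %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# write a data.frame as plain TSV (no quoting, no row names) -- all report
# writers funnel through this so outputs stay byte-stable
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
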