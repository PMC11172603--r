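# Small shared helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a nucleotide string
#' @param x character scalar over A/C/G/T/N (case preserved as upper).
#' @return character scalar
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Deterministic number formatting for emitted text files.  All floating point
# values written by the generator and the pipeline go through this so that
# reruns with the same seed are byte-identical.
fmt_num <- function(x, digits = 6) {
  out <- formatC(x, format = "g", digits = digits)
  gsub(" ", "", out)
}

# Write a data.frame as TSV with a fixed, locale-independent format.
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Pearson correlation p-value via the t transform, two-sided.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
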