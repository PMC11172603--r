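# Sequence-composition statistics and the coding-potential consensus used by
# the screening pipeline.  The consensus is an explicit stand-in for the
# external tool trio (an ORF-length rule, a GC-conditioned null-ORF rule, and
# a protein-domain-hit rule); readers for genuine CPC2 / LGC / pfam_scan
# outputs are provided in io.R so real tool calls can replace the stand-ins.

#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); `N` bases are excluded from the
#' denominator.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stopf("gc_content: sequence must be a non-empty string")
  s <- toupper(sequence)
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stopf("gc_content: sequence contains no A/C/G/T bases")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Length of the longest open reading frame
#'
#' Longest ATG-to-stop ORF on the forward strand across the three reading
#' frames; the returned length includes the stop codon.  ORFs without an
#' in-frame stop inside the sequence do not count.
#'
#' @param sequence nucleotide string.
#' @return length in nt (0 if there is no complete ORF).
#' @export
longest_orf <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stopf("longest_orf: sequence must be a non-empty string")
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 6L) return(0L)
  chars <- strsplit(s, "")[[1]]
  best <- 0L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_start <- codons == "ATG"
    is_stop <- codons %in% .STOP_CODONS
    if (!any(is_start) || !any(is_stop)) next
    stop_pos <- which(is_stop)
    for (i in which(is_start)) {
      nxt <- stop_pos[stop_pos >= i + 1L]
      if (!length(nxt)) break  # no stop downstream of this or any later start
      len <- (nxt[1] - i + 1L) * 3L
      if (len > best) best <- len
    }
  }
  as.integer(best)
}

#' Null ORF-length threshold for a given GC content
#'
#' Under an i.i.d. nucleotide null with p(A)=p(T)=(1-GC)/2 and
#' p(C)=p(G)=GC/2, the number of non-stop codons between a start and the
#' first in-frame stop is geometric with parameter
#' p_stop = p(TAA) + p(TAG) + p(TGA).  The threshold returned is the ORF
#' length (nt, ATG + internal codons + stop) at the `q` quantile of that
#' null distribution.
#'
#' @param gc GC fraction in (0, 1).
#' @param q quantile (default 0.999).
#' @return list with `p_stop` and `orf_nt` (threshold length in nt).
#' @export
orf_null_threshold <- function(gc, q = 0.999) {
  at <- (1 - gc) / 2
  cg <- gc / 2
  p_stop <- at * at * at + at * at * cg + at * cg * at  # TAA + TAG + TGA
  if (p_stop <= 0)   # degenerate composition without T or A: stops impossible
    return(list(p_stop = 0, orf_nt = Inf))
  # internal (non-stop) codon count at quantile q: geometric on 0,1,2,...
  k <- stats::qgeom(q, prob = p_stop)
  list(p_stop = p_stop, orf_nt = 3 * (k + 2))
}

#' Coding-potential consensus verdict
#'
#' Three stand-in predictors: `orf_rule` calls coding when the longest ORF is
#' at least `orf_min` nt; `gc_orf_rule` calls coding when the longest ORF
#' exceeds the 99.9th percentile of the GC-conditioned null ORF-length
#' distribution (see [orf_null_threshold()]); `domain_rule` calls coding when
#' any supplied protein-domain hit has e-value below `domain_max_e`.  The
#' consensus is noncoding only when all three say noncoding.
#'
#' @param sequence nucleotide string.
#' @param domain_hits optional data.frame with `query_id` and `e_value`
#'   (only rows whose `query_id` matches `id` are used when `id` is given;
#'   otherwise all rows count).
#' @param id optional transcript id for domain-hit lookup.
#' @param orf_min ORF-length threshold in nt (default 300).
#' @param domain_max_e domain-hit e-value threshold (default 1e-5).
#' @param null_q null quantile for the GC rule (default 0.999).
#' @return list with `orf_rule`, `gc_orf_rule`, `domain_rule`,
#'   `consensus_noncoding`.
#' @export
coding_potential_consensus <- function(sequence, domain_hits = NULL, id = NULL,
                                       orf_min = 300, domain_max_e = 1e-5,
                                       null_q = 0.999) {
  orf <- longest_orf(sequence)
  gc <- gc_content(sequence)
  orf_rule <- orf >= orf_min
  gc_rule <- orf > orf_null_threshold(gc, null_q)$orf_nt
  dom_rule <- FALSE
  if (!is.null(domain_hits) && nrow(domain_hits)) {
    hits <- domain_hits
    if (!is.null(id)) hits <- hits[hits$query_id == id, , drop = FALSE]
    dom_rule <- any(hits$e_value < domain_max_e)
  }
  list(orf_rule = orf_rule, gc_orf_rule = gc_rule, domain_rule = dom_rule,
       consensus_noncoding = !orf_rule && !gc_rule && !dom_rule)
}
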