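# Class-code classification of assembled transcripts against a reference
# annotation, in the dialect of the Cufflinks comparison step.  Codes handled:
#   "="  full intron-chain identity with a reference transcript
#   "j"  same strand, shares >= 1 complete intron (both boundaries) with a
#        reference transcript, but not the full chain
#   "o"  same-strand exonic overlap without any shared intron
#   "x"  exonic overlap on the opposite strand (antisense)
#   "i"  all exons contained in a single intron of a reference transcript
#   "u"  none of the above (intergenic)
# Priority: = > j > o > x > i > u.  Unstranded queries (".") are treated as
# same-strand for =/j/o/i and can never be "x" (antisense calls need strand
# evidence).  Single-exon "=" uses >= 80% reciprocal overlap against a
# single-exon reference because there is no intron chain to compare.

# internal: exon starts/ends of a transcript as a two-column matrix
.tx_exons <- function(tx) {
  lapply(split(tx[c("start", "end")], tx$transcript_id), as.matrix)
}

# introns of an exon matrix (sorted): (end_i + 1, start_{i+1} - 1)
.introns <- function(ex) {
  if (nrow(ex) < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(ex[-nrow(ex), 2] + 1, ex[-1, 1] - 1)
}

.exonic_overlap <- function(a, b) {
  # total overlapping bases between two exon matrices
  tot <- 0
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a[i, 2], b[, 2]) - pmax(a[i, 1], b[, 1]) + 1
    tot <- tot + sum(ov[ov > 0])
  }
  tot
}

.strand_compatible <- function(q, r) q == "." || r == "." || q == r
.strand_opposite <- function(q, r) (q == "+" && r == "-") || (q == "-" && r == "+")

# Classify one query against one reference transcript; returns the code this
# single comparison supports ("u" when unrelated).
.classify_pair <- function(qex, qstrand, rex, rstrand,
                           single_exon_frac = 0.8) {
  ov <- .exonic_overlap(qex, rex)
  comp <- .strand_compatible(qstrand, rstrand)
  opp <- .strand_opposite(qstrand, rstrand)
  qin <- .introns(qex); rin <- .introns(rex)

  if (comp) {
    if (nrow(qex) > 1L && nrow(rex) > 1L &&
        nrow(qin) == nrow(rin) && all(qin == rin))
      return("=")
    if (nrow(qex) == 1L && nrow(rex) == 1L && ov > 0) {
      qlen <- qex[1, 2] - qex[1, 1] + 1
      rlen <- rex[1, 2] - rex[1, 1] + 1
      if (ov / qlen >= single_exon_frac && ov / rlen >= single_exon_frac)
        return("=")
    }
    if (nrow(qin) > 0 && nrow(rin) > 0) {
      shared <- sum(apply(qin, 1, function(iv)
        any(rin[, 1] == iv[1] & rin[, 2] == iv[2])))
      if (shared > 0) return("j")
    }
    if (ov > 0) return("o")
  }
  if (opp && ov > 0) return("x")
  if (comp && nrow(rin) > 0) {
    qlo <- min(qex[, 1]); qhi <- max(qex[, 2])
    if (any(rin[, 1] <= qlo & rin[, 2] >= qhi)) return("i")
  }
  "u"
}

.CODE_PRIORITY <- c("=" = 1, "j" = 2, "o" = 3, "x" = 4, "i" = 5, "u" = 6)

#' Assign a class code to one assembled transcript
#'
#' Compares a query transcript's exon chain with every reference transcript on
#' the same chromosome and returns the highest-priority applicable code under
#' the priority order `=` > `j` > `o` > `x` > `i` > `u`.
#'
#' @param query transcript table rows for a single transcript.
#' @param reference transcript table for the reference annotation.
#' @param single_exon_frac reciprocal-overlap fraction required for a
#'   single-exon `=` call (default 0.8).
#' @return list with `code` and `matched_reference_id` (NA for `u`).
#' @export
assign_class_code <- function(query, reference, single_exon_frac = 0.8) {
  if (nrow(query) == 0) stopf("query transcript has an empty exon list")
  validate_tx_table(query)
  query <- query[order(query$start), , drop = FALSE]
  qex <- as.matrix(query[c("start", "end")])
  qstrand <- query$strand[1]
  qchr <- query$seqnames[1]

  ref <- reference[reference$seqnames == qchr, , drop = FALSE]
  best_code <- "u"; best_ref <- NA_character_
  if (nrow(ref)) {
    for (rid in unique(ref$transcript_id)) {
      rrows <- ref[ref$transcript_id == rid, , drop = FALSE]
      rex <- as.matrix(rrows[order(rrows$start), c("start", "end")])
      # cheap span rejection
      if (max(rex[, 2]) < min(qex[, 1]) || min(rex[, 1]) > max(qex[, 2])) next
      code <- .classify_pair(qex, qstrand, rex, rrows$strand[1],
                             single_exon_frac)
      if (.CODE_PRIORITY[code] < .CODE_PRIORITY[best_code]) {
        best_code <- code
        best_ref <- rid
      }
      if (best_code == "=") break
    }
  }
  list(code = best_code,
       matched_reference_id = if (best_code == "u") NA_character_ else best_ref)
}

#' Batch class-code comparison of two annotations
#'
#' Classifies every query transcript against the reference using an interval
#' index over reference transcript spans; row-for-row equivalent to calling
#' [assign_class_code()] per query, and independent of query input order.
#'
#' @param queries transcript table of assembled transcripts.
#' @param reference transcript table of the reference annotation.
#' @param single_exon_frac see [assign_class_code()].
#' @return data.frame with `transcript_id`, `class_code`,
#'   `matched_reference_id`, sorted by transcript id.
#' @export
compare_annotations <- function(queries, reference, single_exon_frac = 0.8) {
  if (nrow(queries) == 0)
    return(data.frame(transcript_id = character(0), class_code = character(0),
                      matched_reference_id = character(0),
                      stringsAsFactors = FALSE))
  validate_tx_table(queries)
  validate_tx_table(reference)

  # a transcript id reused across chromosomes or gene ids is a duplicate
  qsplit <- split(seq_len(nrow(queries)), queries$transcript_id)
  for (tid in names(qsplit)) {
    idx <- qsplit[[tid]]
    if (length(unique(queries$seqnames[idx])) > 1L ||
        length(unique(queries$gene_id[idx])) > 1L)
      stopf("duplicate transcript_id in query set: %s", tid)
  }

  # span index for the reference: one range per reference transcript,
  # padded queries fetched with findOverlaps
  rsplit <- split(seq_len(nrow(reference)), reference$transcript_id)
  rids <- names(rsplit)
  rspan <- do.call(rbind, lapply(rsplit, function(idx)
    c(min(reference$start[idx]), max(reference$end[idx]))))
  rgr <- GenomicRanges::GRanges(
    seqnames = vapply(rsplit, function(idx) reference$seqnames[idx[1]], character(1)),
    ranges = IRanges::IRanges(rspan[, 1], rspan[, 2]))

  rex_list <- lapply(rsplit, function(idx) {
    o <- idx[order(reference$start[idx])]
    list(ex = cbind(reference$start[o], reference$end[o]),
         strand = reference$strand[idx[1]])
  })

  qids <- sort(names(qsplit))
  out <- data.frame(transcript_id = qids,
                    class_code = "u",
                    matched_reference_id = NA_character_,
                    stringsAsFactors = FALSE)
  qgr <- GenomicRanges::GRanges(
    seqnames = vapply(qsplit[qids], function(idx) queries$seqnames[idx[1]], character(1)),
    ranges = IRanges::IRanges(
      vapply(qsplit[qids], function(idx) min(queries$start[idx]), numeric(1)),
      vapply(qsplit[qids], function(idx) max(queries$end[idx]), numeric(1))))
  hits <- GenomicRanges::findOverlaps(qgr, rgr, ignore.strand = TRUE)
  hit_by_q <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  for (qi in seq_along(qids)) {
    idx <- qsplit[[qids[qi]]]
    o <- idx[order(queries$start[idx])]
    qex <- cbind(queries$start[o], queries$end[o])
    qstrand <- queries$strand[idx[1]]
    cands <- hit_by_q[[as.character(qi)]]
    if (is.null(cands)) next
    best_code <- "u"; best_ref <- NA_character_
    for (ri in cands) {
      r <- rex_list[[ri]]
      code <- .classify_pair(qex, qstrand, r$ex, r$strand, single_exon_frac)
      if (.CODE_PRIORITY[code] < .CODE_PRIORITY[best_code]) {
        best_code <- code; best_ref <- rids[ri]
      }
      if (best_code == "=") break
    }
    out$class_code[qi] <- best_code
    out$matched_reference_id[qi] <- if (best_code == "u") NA_character_ else best_ref
  }
  out
}
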