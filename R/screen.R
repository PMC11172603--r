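# The multi-stage lncRNA screening pipeline: class-code retention, length
# floor, known-RNA removal, coding-potential consensus, miRNA-precursor
# removal and expression floor, with a per-stage elimination report
# (first-failure attribution) and feature statistics for the accepted set.

#' Expression floor filter
#'
#' A transcript survives when its maximum FPKM over all samples reaches the
#' threshold (inclusive).
#'
#' @param matrix FPKM matrix.
#' @param ids transcript ids to test (must all be in the matrix).
#' @param threshold FPKM floor (default 0.5).
#' @return character vector of surviving ids.
#' @export
expression_floor <- function(matrix, ids = rownames(matrix), threshold = 0.5) {
  missing <- setdiff(ids, rownames(matrix))
  if (length(missing))
    stopf("expression_floor: transcripts absent from matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  mx <- apply(matrix[ids, , drop = FALSE], 1, max)
  ids[mx >= threshold]
}

#' Run the lncRNA screening pipeline
#'
#' Applies, in order: (1) keep class codes in `keep_codes`; (2) keep length
#' `> min_length - 1` nt; (3) drop transcripts with known-RNA similarity
#' hits; (4) keep coding-potential consensus noncoding; (5) drop transcripts
#' with miRNA-precursor hits; (6) keep transcripts passing the expression
#' floor.  Each eliminated transcript records its first failing stage.
#'
#' @param codes data.frame from [compare_annotations()].
#' @param sequences named character vector of transcript sequences.
#' @param known_rna known mRNA/ncRNA database (sequences or hit table).
#' @param mirna miRNA database (sequences or hit table).
#' @param matrix FPKM matrix covering the candidates.
#' @param domain_hits optional domain-hit table for the consensus.
#' @param keep_codes class codes retained at stage 1.
#' @param min_length minimum transcript length (strictly greater than 200 by
#'   default, i.e. >= 201 nt).
#' @param sim_max_e,sim_min_identity similarity-screen thresholds.
#' @param orf_min ORF-length threshold of the consensus.
#' @param fpkm_floor expression floor.
#' @param locus_ids optional named vector transcript -> locus for the report.
#' @return object of class `screening_report`: list with `stages`
#'   (per-stage input/surviving counts), `eliminated` (id -> stage),
#'   `accepted` (ids), `features` (length/exons/GC/chromosome per accepted
#'   transcript when `codes` carries them).
#' @export
run_screening_pipeline <- function(codes, sequences, known_rna, mirna, matrix,
                                   domain_hits = NULL,
                                   keep_codes = c("i", "o", "u", "j", "x"),
                                   min_length = 201,
                                   sim_max_e = 1e-10, sim_min_identity = 90,
                                   orf_min = 300, fpkm_floor = 0.5,
                                   locus_ids = NULL) {
  ids0 <- codes$transcript_id
  miss <- setdiff(ids0, names(sequences))
  if (length(miss))
    stopf("screening: transcripts without sequence: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(ids0, rownames(matrix))
  if (length(miss))
    stopf("screening: transcripts absent from FPKM matrix: %s",
          paste(utils::head(miss, 5), collapse = ", "))

  eliminated <- character(0)
  stages <- data.frame(stage = character(0), input = integer(0),
                       surviving = integer(0))
  note <- function(stage, before, after) {
    gone <- setdiff(before, after)
    eliminated[gone] <<- stage
    stages <<- rbind(stages, data.frame(stage = stage,
                                        input = length(before),
                                        surviving = length(after)))
    after
  }

  ids <- note("class_code", ids0,
              ids0[codes$class_code %in% keep_codes])
  len <- nchar(sequences[ids])
  ids <- note("length", ids, ids[len >= min_length])
  if (length(ids)) {
    flagged <- similarity_screen(sequences[ids], known_rna,
                                 max_e = sim_max_e,
                                 min_identity = sim_min_identity)
    ids <- note("known_rna", ids, setdiff(ids, flagged))
  } else ids <- note("known_rna", ids, ids)
  verdicts <- vapply(ids, function(i)
    coding_potential_consensus(sequences[[i]], domain_hits, id = i,
                               orf_min = orf_min)$consensus_noncoding,
    logical(1))
  ids <- note("coding", ids, ids[verdicts])
  if (length(ids)) {
    flagged <- similarity_screen(sequences[ids], mirna, max_e = sim_max_e,
                                 min_identity = sim_min_identity)
    ids <- note("mirna", ids, setdiff(ids, flagged))
  } else ids <- note("mirna", ids, ids)
  ids <- note("fpkm", ids, expression_floor(matrix, ids, fpkm_floor))

  feats <- data.frame(
    transcript_id = ids,
    locus_id = if (!is.null(locus_ids)) unname(locus_ids[ids]) else NA_character_,
    class_code = codes$class_code[match(ids, codes$transcript_id)],
    length = nchar(sequences[ids]),
    gc = vapply(ids, function(i) gc_content(sequences[[i]]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  out <- list(stages = stages, eliminated = eliminated, accepted = ids,
              features = feats)
  class(out) <- "screening_report"
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat("lncRNA screening report\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-10s %5d -> %5d\n", x$stages$stage[i], x$stages$input[i],
                x$stages$surviving[i]))
  cat(sprintf("accepted: %d transcripts", length(x$accepted)))
  if (length(x$accepted))
    cat(sprintf(" | mean length %.0f nt | mean GC %.3f",
                mean(x$features$length), mean(x$features$gc)))
  cat("\n")
  invisible(x)
}

#' Feature summary of an accepted lncRNA set
#'
#' @param report a `screening_report`.
#' @param tx optional transcript table to add exon counts and chromosomes.
#' @return data.frame with per-transcript length, GC, exon count and
#'   chromosome, plus a `summary` attribute (means and class-code counts).
#' @export
lncrna_features <- function(report, tx = NULL) {
  f <- report$features
  if (!is.null(tx)) {
    ex <- table(tx$transcript_id)
    f$exons <- as.integer(ex[f$transcript_id])
    f$chromosome <- tx$seqnames[match(f$transcript_id, tx$transcript_id)]
  }
  attr(f, "summary") <- list(
    n = nrow(f), mean_length = mean(f$length), mean_gc = mean(f$gc),
    class_counts = table(f$class_code))
  f
}
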