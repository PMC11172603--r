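# Motif scanning against supplied consensus models (IUPAC allowed) and
# motif-architecture classification of homolog-family sequences.  The
# architecture string lists the first occurrence of each distinct motif in
# 5'->3' order after orientation-normalising the sequence to the majority
# strand of its motif occurrences; "312" defines class 1 and "213" class 2
# of the hyperosmolarity-stress-activated lncRNA family.

#' Construct a motif model
#'
#' @param motif_id small integer identifier.
#' @param consensus nucleotide consensus (IUPAC codes allowed), length >= 6.
#' @param max_mismatches allowed Hamming mismatches, < length/3.
#' @return motif model (list).
#' @export
motif_model <- function(motif_id, consensus, max_mismatches = 1) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 6)
    stopf("motif consensus must be at least 6 nt")
  if (max_mismatches >= nchar(consensus) / 3)
    stopf("max_mismatches must be < consensus length / 3")
  list(motif_id = as.integer(motif_id), consensus = consensus,
       max_mismatches = as.integer(max_mismatches))
}

# all matches of one consensus on one strand; returns starts and scores
.scan_one <- function(subject, consensus, max_mm) {
  hits <- Biostrings::matchPattern(consensus, subject,
                                   max.mismatch = max_mm, fixed = FALSE)
  if (!length(hits)) return(NULL)
  starts <- BiocGenerics::start(hits)
  mm <- vapply(seq_along(hits), function(i)
    Biostrings::neditAt(consensus, subject, at = starts[i], fixed = FALSE),
    integer(1))
  list(start = starts, score = nchar(consensus) - mm)
}

#' Scan a sequence for motif occurrences
#'
#' Finds all positions on both strands where the Hamming distance to the
#' consensus is within the model's allowance, scores each occurrence by the
#' number of matching positions, and resolves overlapping occurrences of the
#' same motif greedily by score, then leftmost start.
#'
#' @param sequence nucleotide string.
#' @param motifs list of motif models (see [motif_model()]).
#' @return data.frame with `motif_id`, `start` (1-based, on the given
#'   sequence), `strand`, `score`, sorted by start.
#' @export
scan_motifs <- function(sequence, motifs) {
  s <- Biostrings::DNAString(toupper(sequence))
  out <- list()
  for (m in motifs) {
    if (length(s) < nchar(m$consensus)) next
    occ <- list()
    fwd <- .scan_one(s, m$consensus, m$max_mismatches)
    if (!is.null(fwd))
      occ[[length(occ) + 1L]] <- data.frame(start = fwd$start, strand = "+",
                                            score = fwd$score)
    rc <- .scan_one(s, revcomp_chr(m$consensus), m$max_mismatches)
    if (!is.null(rc))
      occ[[length(occ) + 1L]] <- data.frame(start = rc$start, strand = "-",
                                            score = rc$score)
    if (!length(occ)) next
    occ <- do.call(rbind, occ)
    occ <- occ[order(-occ$score, occ$start), , drop = FALSE]
    w <- nchar(m$consensus)
    taken <- logical(0); kept <- integer(0); ends <- integer(0); starts <- integer(0)
    for (i in seq_len(nrow(occ))) {
      st <- occ$start[i]; en <- st + w - 1L
      if (!length(starts) || all(en < starts | st > ends)) {
        kept <- c(kept, i); starts <- c(starts, st); ends <- c(ends, en)
      }
    }
    occ <- occ[kept, , drop = FALSE]
    occ$motif_id <- m$motif_id
    out[[length(out) + 1L]] <- occ
  }
  if (!length(out))
    return(data.frame(motif_id = integer(0), start = integer(0),
                      strand = character(0), score = integer(0)))
  res <- do.call(rbind, out)[, c("motif_id", "start", "strand", "score")]
  res <- res[order(res$start, res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify the motif architecture of a sequence
#'
#' When the majority strand of the occurrences is "-", the coordinate system
#' is flipped (as if the sequence were reverse-complemented) before reading
#' the architecture, so transcription-direction differences between family
#' members do not change the label.  The architecture string lists the first
#' occurrence of each distinct motif 5'->3'; "312" is class1, "213" class2,
#' anything else "other".  Motifs occurring more than once are reported as
#' expansions.
#'
#' @param occurrences data.frame from [scan_motifs()].
#' @param seq_length sequence length in nt (needed to flip coordinates; only
#'   used when the majority strand is "-").
#' @return list with `architecture`, `class_label`, `expansions` (named
#'   integer vector of copy counts > 1), `oriented_minus`.
#' @export
classify_architecture <- function(occurrences, seq_length = NULL) {
  occ <- occurrences
  if (nrow(occ) == 0)
    return(list(architecture = "", class_label = "other",
                expansions = integer(0), oriented_minus = FALSE))
  minus <- sum(occ$strand == "-") > nrow(occ) / 2
  if (minus) {
    if (is.null(seq_length))
      stopf("classify_architecture: seq_length required to orient a minus-strand architecture")
    occ$start <- seq_length - occ$start + 1L  # flip 5'->3' reading direction
  }
  occ <- occ[order(occ$start), , drop = FALSE]
  first <- occ[!duplicated(occ$motif_id), , drop = FALSE]
  arch <- paste(first$motif_id, collapse = "")
  class_label <- if (arch == "312") "class1" else
                 if (arch == "213") "class2" else "other"
  counts <- table(occ$motif_id)
  expansions <- counts[counts > 1]
  expansions <- stats::setNames(as.integer(expansions), names(expansions))
  list(architecture = arch, class_label = class_label,
       expansions = expansions, oriented_minus = minus)
}

#' Architecture classification for a set of sequences
#'
#' @param seqs named character vector of sequences.
#' @param motifs list of motif models.
#' @return data.frame with `sequence_id`, `architecture`, `class_label`,
#'   `n_occurrences`, `expanded_motifs`.
#' @export
classify_family_architectures <- function(seqs, motifs) {
  rows <- lapply(names(seqs), function(id) {
    occ <- scan_motifs(seqs[[id]], motifs)
    cl <- classify_architecture(occ, seq_length = nchar(seqs[[id]]))
    data.frame(sequence_id = id, architecture = cl$architecture,
               class_label = cl$class_label, n_occurrences = nrow(occ),
               expanded_motifs = paste(names(cl$expansions), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
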