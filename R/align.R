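# Built-in nucleotide similarity search used for the known-RNA screen, the
# miRNA-precursor screen and ortholog counting: exact k-mer seeding (k = 11)
# followed by banded Smith-Waterman extension with affine gaps
# (match +1, mismatch -2, gap open 5, extend 2; a gap of length L costs
# 5 + 2L).  E-values use the Karlin-Altschul form E = K * m * n * exp(-lambda*S)
# with the documented stand-in calibration K = 0.1, lambda = 0.5; screening
# decisions rest on identity and alignment score, not on the absolute E-value
# scale.  Pre-computed BLAST outfmt-6 hit tables can be supplied instead of
# sequences at every entry point.

.KMER_K <- 11L

.kmers <- function(s, k = .KMER_K) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# best seed diagonal (subject_pos - query_pos) shared by a query/subject pair,
# or NA when no k-mer is shared
.best_diagonal <- function(qk, sk_split) {
  common <- intersect(names(sk_split), unique(qk))
  if (!length(common)) return(NA_integer_)
  qpos <- split(seq_along(qk), qk)
  diffs <- unlist(lapply(common, function(km)
    as.vector(outer(sk_split[[km]], qpos[[km]], `-`))), use.names = FALSE)
  tab <- table(diffs)
  as.integer(names(tab)[which.max(tab)])
}

#' Banded Smith-Waterman local alignment
#'
#' Affine-gap local alignment restricted to a diagonal band around
#' `diagonal` (subject position minus query position).
#'
#' @param query,subject nucleotide strings.
#' @param diagonal band centre (0 = main diagonal).
#' @param band half-width of the band in cells.
#' @param match,mismatch,gap_open,gap_extend scoring parameters; a gap of
#'   length L costs `gap_open + gap_extend * L`.
#' @return list with `score`, `matches`, `align_length` (aligned columns,
#'   gaps included), `identity` (percent over aligned columns), and the
#'   1-based end coordinates `q_end`, `s_end`.  Score 0 means no positive
#'   local alignment inside the band.
#' @export
banded_sw <- function(query, subject, diagonal = 0L, band = 25L,
                      match = 1, mismatch = -2, gap_open = 5, gap_extend = 2) {
  q <- strsplit(toupper(query), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  m <- length(q); n <- length(s)
  w <- as.integer(band); d0 <- as.integer(diagonal)
  bw <- 2L * w + 1L
  NEG <- -1e9
  gopen <- gap_open + gap_extend

  # column index within the band for subject position j at query row i:
  # c = j - (i + d0) + w + 1
  H <- matrix(0, nrow = m + 1L, ncol = bw + 2L)
  E <- matrix(NEG, nrow = m + 1L, ncol = bw + 2L)
  F <- matrix(NEG, nrow = m + 1L, ncol = bw + 2L)
  # pointer codes: 0 none, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  P <- matrix(0L, nrow = m + 1L, ncol = bw + 2L)

  best <- 0; bi <- 0L; bc <- 0L
  for (i in 1L:m) {
    jlo <- max(1L, i + d0 - w); jhi <- min(n, i + d0 + w)
    if (jlo > jhi) next
    for (j in jlo:jhi) {
      cc <- j - (i + d0) + w + 2L          # this row's band column
      cd <- cc + 1L                        # previous row, same j -> shifted
      sub <- if (q[i] == s[j]) match else mismatch
      # E: gap in query (consume subject), depends on same row, j-1
      e <- max(H[i + 1L, cc - 1L] - gopen, E[i + 1L, cc - 1L] - gap_extend)
      # F: gap in subject (consume query), depends on previous row, same j
      f <- max(H[i, cd] - gopen, F[i, cd] - gap_extend)
      h_diag <- H[i, cd - 1L] + sub
      h <- max(0, h_diag, e, f)
      H[i + 1L, cc] <- h; E[i + 1L, cc] <- e; F[i + 1L, cc] <- f
      P[i + 1L, cc] <- if (h == 0) 0L else if (h == h_diag) 1L
                       else if (h == f) 2L else 3L
      if (h > best) { best <- h; bi <- i; bc <- cc }
    }
  }
  if (best <= 0)
    return(list(score = 0, matches = 0L, align_length = 0L, identity = 0,
                q_end = 0L, s_end = 0L))

  # traceback for matches / aligned columns
  i <- bi; cc <- bc
  matches <- 0L; alen <- 0L
  while (i >= 1L) {
    p <- P[i + 1L, cc]
    if (p == 0L) break
    j <- cc + (i + d0) - w - 2L
    if (p == 1L) {
      alen <- alen + 1L
      if (q[i] == s[j]) matches <- matches + 1L
      i <- i - 1L; cc <- cc  # j decreases with i: same band column
    } else if (p == 2L) {    # gap in subject: move up
      alen <- alen + 1L
      i <- i - 1L; cc <- cc + 1L
    } else {                 # gap in query: move left
      alen <- alen + 1L
      cc <- cc - 1L
    }
    if (P[i + 1L, cc] == 0L && H[i + 1L, cc] == 0) break
  }
  list(score = best, matches = matches, align_length = alen,
       identity = 100 * matches / alen,
       q_end = bi, s_end = bc + (bi + d0) - w - 2L)
}

#' E-value of a local alignment score
#' @param score raw Smith-Waterman score.
#' @param m,n query and subject lengths.
#' @param K,lambda Karlin-Altschul constants (stand-in calibration).
#' @return E-value.
#' @export
alignment_evalue <- function(score, m, n, K = 0.1, lambda = 0.5) {
  K * m * n * exp(-lambda * score)
}

# search one query against a subject database; returns a hit data.frame
.search_query <- function(qid, qseq, subjects, sk_index, band = 25L) {
  qk <- .kmers(qseq)
  hits <- list()
  for (sid in names(subjects)) {
    d <- .best_diagonal(qk, sk_index[[sid]])
    if (is.na(d)) next
    aln <- banded_sw(qseq, subjects[[sid]], diagonal = d, band = band)
    if (aln$score <= 0) next
    ev <- alignment_evalue(aln$score, nchar(qseq), nchar(subjects[[sid]]))
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = qid, subject_id = sid, percent_identity = aln$identity,
      alignment_length = aln$align_length, e_value = ev,
      bitscore = aln$score, stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), alignment_length = integer(0),
                      e_value = numeric(0), bitscore = numeric(0)))
  do.call(rbind, hits)
}

#' Search queries against a subject database
#'
#' @param queries named character vector of query sequences.
#' @param subjects named character vector of subject sequences.
#' @param band band half-width for the extension step.
#' @return hit data.frame (`query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `e_value`, `bitscore`).
#' @export
similarity_search <- function(queries, subjects, band = 25L) {
  if (!length(subjects)) stopf("similarity_search: empty subject database")
  sk_index <- lapply(subjects, function(s) {
    km <- .kmers(s)
    split(seq_along(km), km)
  })
  out <- lapply(names(queries), function(qid)
    .search_query(qid, queries[[qid]], subjects, sk_index, band))
  do.call(rbind, out)
}

#' Flag queries with similarity hits passing thresholds
#'
#' A query is flagged when at least one hit passes both the E-value and the
#' identity threshold.  `subjects` may be a named character vector of
#' sequences (the built-in search is run) or a pre-computed hit table
#' (columns as in [read_blast_tab()]).
#'
#' @param queries named character vector of query sequences (or, when
#'   `subjects` is a hit table, a character vector of query ids).
#' @param subjects subject sequences or hit data.frame.
#' @param max_e maximum E-value (default 1e-10).
#' @param min_identity minimum percent identity (default 90).
#' @return character vector of flagged query ids.
#' @export
similarity_screen <- function(queries, subjects, max_e = 1e-10,
                              min_identity = 90) {
  if (max_e <= 0 || min_identity < 0)
    stopf("similarity_screen: thresholds must be positive")
  if (is.data.frame(subjects)) {
    hits <- subjects
  } else {
    if (!length(subjects))
      stopf("similarity_screen: empty subject database")
    hits <- similarity_search(queries, subjects)
  }
  pass <- hits$e_value < max_e & hits$percent_identity > min_identity
  sort(unique(hits$query_id[pass]))
}

#' Count queries with orthologs per species
#'
#' For each species, counts the queries with at least one hit passing the
#' E-value threshold (a query counts once per species regardless of hit
#' multiplicity).  Each species entry may be a named character vector of
#' sequences or a pre-computed hit table.
#'
#' @param query_lncrnas named character vector of query sequences.
#' @param species_sets named list, one element per species.
#' @param max_e E-value threshold (default 1e-5).
#' @param min_identity identity threshold (default 0: E-value only).
#' @return named integer vector of counts per species.
#' @export
count_orthologs <- function(query_lncrnas, species_sets, max_e = 1e-5,
                            min_identity = 0) {
  if (!length(species_sets)) stopf("count_orthologs: no species sets supplied")
  out <- integer(length(species_sets))
  names(out) <- names(species_sets)
  for (sp in names(species_sets)) {
    set <- species_sets[[sp]]
    if (!is.data.frame(set) && !length(set)) {
      warning(sprintf("species set '%s' is empty; count 0", sp))
      out[sp] <- 0L
      next
    }
    flagged <- similarity_screen(query_lncrnas, set, max_e = max_e,
                                 min_identity = min_identity)
    out[sp] <- length(intersect(flagged, names(query_lncrnas)))
  }
  out
}
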