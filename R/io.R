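# Readers and writers for the plain-text formats the pipeline exchanges:
# GTF transcript models, FASTA sequences, FPKM/design tables, BLAST outfmt-6
# hit tables, domain-hit tables, coding-potential tool outputs and MEME motifs.
#
# The in-memory exchange format for transcript models is an exon-level
# data.frame ("transcript table") with columns
#   transcript_id, gene_id, seqnames, strand, start, end
# using 1-based inclusive coordinates (the IRanges convention), one row per
# exon, exons of a transcript sorted by start and non-overlapping.

#' Validate a transcript table
#'
#' @param tx data.frame with columns `transcript_id`, `gene_id`, `seqnames`,
#'   `strand` (one of `+`, `-`, `.`), `start`, `end` (1-based inclusive).
#' @return the table, invisibly, with exons sorted within transcript.
#' @export
validate_tx_table <- function(tx) {
  need <- c("transcript_id", "gene_id", "seqnames", "strand", "start", "end")
  miss <- setdiff(need, names(tx))
  if (length(miss))
    stopf("transcript table is missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(tx) == 0) return(invisible(tx))
  if (any(tx$end < tx$start))
    stopf("transcript table has exons with end < start")
  if (!all(tx$strand %in% c("+", "-", ".")))
    stopf("strand must be one of '+', '-', '.'")
  tx <- tx[order(tx$transcript_id, tx$start), , drop = FALSE]
  # exons within a transcript must not overlap
  by_tx <- split(seq_len(nrow(tx)), tx$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- tx$start[idx]; e <- tx$end[idx]
      if (any(s[-1] <= e[-length(e)]))
        stopf("overlapping exons in transcript %s", tx$transcript_id[idx[1]])
    }
  }
  invisible(tx)
}

#' Read transcript models from a GTF file
#'
#' Keeps `exon` features only and returns the exon-level transcript table.
#'
#' @param path GTF file.
#' @return transcript table (see [validate_tx_table()]).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tx <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  tx$strand[tx$strand == "*"] <- "."
  tx <- tx[order(tx$transcript_id, tx$start), , drop = FALSE]
  rownames(tx) <- NULL
  validate_tx_table(tx)
  tx
}

#' Write a transcript table as GTF
#'
#' Emits one `transcript` line and its `exon` lines per transcript, in a fixed
#' attribute order, so output is byte-stable for a given table.
#'
#' @param tx transcript table.
#' @param path output file.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path, source = "stresslnc") {
  validate_tx_table(tx)
  tx <- tx[order(tx$seqnames, tx$transcript_id, tx$start), , drop = FALSE]
  lines <- character(0)
  for (tid in unique(tx$transcript_id)) {
    ex <- tx[tx$transcript_id == tid, , drop = FALSE]
    gid <- ex$gene_id[1]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    strand <- if (ex$strand[1] == ".") "." else ex$strand[1]
    lines <- c(lines,
      sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              ex$seqnames[1], source, min(ex$start), max(ex$end), strand, attr_str),
      sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
              ex$seqnames, source, ex$start, ex$end, strand, attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read an FPKM matrix (transcripts x samples) from TSV
#'
#' First column is the transcript id; remaining columns are samples.
#' @param path TSV file.
#' @return numeric matrix with transcript ids as rownames.
#' @export
read_fpkm <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (anyNA(m)) stopf("FPKM matrix %s contains missing values", path)
  if (any(m < 0)) stopf("FPKM matrix %s contains negative values", path)
  m
}

#' Write an FPKM matrix to TSV
#' @param m numeric matrix with rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read the sample design table
#'
#' Columns: `sample_id`, `genotype` (WT/mutant), `tissue` (shoot/root),
#' `treatment` (control/NaCl/sorbitol), `replicate`.
#' @param path TSV file.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read_tsv(path)
  need <- c("sample_id", "genotype", "tissue", "treatment", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("design table missing columns: %s", paste(miss, collapse = ", "))
  d
}

#' Read a 12-column BLAST tabular (outfmt 6) hit file
#' @param path hit table.
#' @return data.frame with the standard columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    stopf("%s: expected 12 tab-separated columns, found %d", path, ncol(df))
  names(df) <- cols
  df
}

#' Read a domain-hit table
#'
#' Expects a TSV with at least `query_id` and `e_value` columns (a
#' Pfam-scan-style per-domain hit list).
#' @param path TSV file.
#' @return data.frame.
#' @export
read_domain_hits <- function(path) {
  df <- tryCatch(read_tsv(path), error = function(e)
    stopf("%s: cannot parse domain-hit table: %s", path, conditionMessage(e)))
  need <- c("query_id", "e_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    # locate the first offending line for the error message
    stopf("%s: line 1: domain-hit table missing columns: %s",
          path, paste(miss, collapse = ", "))
  }
  ev <- suppressWarnings(as.numeric(df$e_value))
  if (anyNA(ev)) {
    bad <- which(is.na(ev))[1]
    stopf("%s: line %d: non-numeric e_value '%s'", path, bad + 1L,
          df$e_value[bad])
  }
  df$e_value <- ev
  df
}

#' Read CPC2 output
#'
#' Parses the tabular output of the CPC2 coding-potential tool and returns the
#' set of transcripts called `coding`.
#' @param path CPC2 result file (columns include the id and a `label` column
#'   with values `coding`/`noncoding`).
#' @return character vector of coding transcript ids.
#' @export
read_cpc2 <- function(path) {
  lines <- readLines(path)
  lines[1] <- sub("^#", "", lines[1])  # CPC2 prefixes its header with '#'
  df <- utils::read.delim(text = lines, header = TRUE,
                          stringsAsFactors = FALSE)
  lab <- names(df)[grepl("label", names(df), ignore.case = TRUE)][1]
  if (is.na(lab)) stopf("%s: no 'label' column found (is this CPC2 output?)", path)
  df[[1]][tolower(df[[lab]]) == "coding"]
}

#' Read LGC output
#'
#' Parses LGC's tabular output and returns ids called coding.
#' @param path LGC result file with an id column and a `Coding`/`Noncoding`
#'   call column.
#' @return character vector of coding transcript ids.
#' @export
read_lgc <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  call_col <- names(df)[vapply(df, function(x)
    any(tolower(x) %in% c("coding", "noncoding")), logical(1))][1]
  if (is.na(call_col)) stopf("%s: no Coding/Noncoding column found", path)
  df[[1]][tolower(df[[call_col]]) == "coding"]
}

#' Read pfam_scan output
#'
#' Parses the whitespace-delimited pfam_scan.pl output into a domain-hit table
#' usable by [coding_potential_consensus()].
#' @param path pfam_scan output file.
#' @return data.frame with `query_id` and `e_value`.
#' @export
read_pfam_scan <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(data.frame(query_id = character(0), e_value = numeric(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 13)) {
    bad <- which(nf < 13)[1]
    stopf("%s: line %d: expected >= 13 fields, found %d", path, bad, nf[bad])
  }
  data.frame(
    query_id = vapply(parts, `[[`, character(1), 1),
    e_value = as.numeric(vapply(parts, `[[`, character(1), 13)),
    stringsAsFactors = FALSE
  )
}

#' Read motif models from a consensus TSV
#'
#' Columns: `motif_id` (small integer), `consensus` (IUPAC nucleotide string),
#' `max_mismatches`.
#' @param path TSV file.
#' @return list of motif models (each a list with `motif_id`, `consensus`,
#'   `max_mismatches`).
#' @export
read_motif_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("motif_id", "consensus", "max_mismatches")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: motif table missing columns: %s", path, paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    motif_model(df$motif_id[i], df$consensus[i], df$max_mismatches[i]))
}

#' Read motifs from MEME text-format output
#'
#' Extracts each motif's multilevel consensus so MEME-discovered motifs can
#' replace the built-in consensus models.
#' @param path MEME text output file.
#' @param max_mismatches mismatch allowance attached to every motif.
#' @return list of motif models.
#' @export
read_meme_motifs <- function(path, max_mismatches = 2) {
  lines <- readLines(path)
  hdr <- grep("^MOTIF\\b", lines, value = TRUE)
  if (!length(hdr)) stopf("%s: no MOTIF blocks found", path)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    toks <- strsplit(trimws(hdr[i]), "\\s+")[[1]]
    cons <- toks[2]
    out[[i]] <- motif_model(i, cons, max_mismatches)
  }
  out
}
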