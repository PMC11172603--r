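# Cis-target prediction by genomic window plus expression correlation, TF
# family tallying and hypergeometric GO enrichment.  Window distance is the
# gap between locus spans (closest ends, strand-agnostic), 0 when the spans
# overlap; the correlation rule is one-sided positive (PCC >= 0.9) by
# default, with a signed |PCC| option.

# locus span table from a transcript table: one row per gene_id
.locus_spans <- function(tx) {
  sp <- split(seq_len(nrow(tx)), tx$gene_id)
  data.frame(
    gene_id = names(sp),
    seqnames = vapply(sp, function(i) tx$seqnames[i[1]], character(1)),
    start = vapply(sp, function(i) min(tx$start[i]), numeric(1)),
    end = vapply(sp, function(i) max(tx$end[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Protein-coding genes within a genomic window of lncRNA loci
#'
#' A gene qualifies when the gap between its span and the lncRNA locus span
#' is at most `window` nt (inclusive at exactly `window`); overlapping spans
#' have distance 0.  Both flanks are searched regardless of strand.
#'
#' @param lnc_tx transcript table of lncRNA loci.
#' @param gene_tx transcript table of candidate target genes.
#' @param window maximum gap in nt (default 100000).
#' @return data.frame with `lncrna_gene`, `pcg_gene`, `distance`.
#' @export
window_neighbors <- function(lnc_tx, gene_tx, window = 100000) {
  lnc <- .locus_spans(lnc_tx)
  pcg <- .locus_spans(gene_tx)
  missing_chr <- setdiff(unique(lnc$seqnames), unique(pcg$seqnames))
  if (length(missing_chr))
    stopf("window_neighbors: chromosome(s) absent from gene annotation: %s",
          paste(missing_chr, collapse = ", "))
  lgr <- GenomicRanges::GRanges(lnc$seqnames, IRanges::IRanges(lnc$start, lnc$end))
  pgr <- GenomicRanges::GRanges(pcg$seqnames, IRanges::IRanges(pcg$start, pcg$end))
  hits <- GenomicRanges::findOverlaps(lgr, pgr, maxgap = window,
                                      ignore.strand = TRUE)
  d <- GenomicRanges::distance(lgr[S4Vectors::queryHits(hits)],
                               pgr[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  data.frame(lncrna_gene = lnc$gene_id[S4Vectors::queryHits(hits)],
             pcg_gene = pcg$gene_id[S4Vectors::subjectHits(hits)],
             distance = as.numeric(d),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cis-regulated target pairs
#'
#' Computes the Pearson correlation across all samples for each candidate
#' lncRNA-gene pair and flags the pairs that pass the cis rule:
#' PCC >= `pcc_min`, p < `p_max`, distance <= window (already enforced by
#' the candidate table).
#'
#' @param candidates data.frame from [window_neighbors()], with columns
#'   `lncrna_id`/`lncrna_gene` and `pcg_id`/`pcg_gene` resolvable in the
#'   matrix via `lnc_map`/`pcg_map` (identity by default).
#' @param matrix FPKM matrix (transcripts x samples).
#' @param lnc_map,pcg_map optional named vectors mapping gene/locus ids to
#'   matrix row ids.
#' @param pcc_min correlation threshold (default 0.9).
#' @param p_max p-value threshold (default 0.05).
#' @param signed when TRUE the rule is |PCC| >= pcc_min.
#' @param samples optional subset of sample columns.
#' @return data.frame with `lncrna_id`, `pcg_id`, `distance`, `pcc`,
#'   `p_value`, `undefined`, `passes`.
#' @export
cis_pairs <- function(candidates, matrix, lnc_map = NULL, pcg_map = NULL,
                      pcc_min = 0.9, p_max = 0.05, signed = FALSE,
                      samples = NULL) {
  if (!is.null(samples)) matrix <- matrix[, samples, drop = FALSE]
  lids <- candidates$lncrna_id %||% candidates$lncrna_gene
  pids <- candidates$pcg_id %||% candidates$pcg_gene
  if (!is.null(lnc_map)) lids <- unname(lnc_map[lids])
  if (!is.null(pcg_map)) pids <- unname(pcg_map[pids])
  missing <- setdiff(unique(c(lids, pids)), rownames(matrix))
  if (length(missing))
    stopf("cis_pairs: ids absent from matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  n <- ncol(matrix)
  pcc <- p <- numeric(length(lids))
  undef <- logical(length(lids))
  for (i in seq_along(lids)) {
    x <- matrix[lids[i], ]; y <- matrix[pids[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      undef[i] <- TRUE; pcc[i] <- NA_real_; p[i] <- NA_real_
    } else {
      pcc[i] <- stats::cor(x, y)
      p[i] <- cor_pvalue(pcc[i], n)
    }
  }
  crit <- if (signed) abs(pcc) else pcc
  passes <- !undef & crit >= pcc_min & p < p_max
  passes[is.na(passes)] <- FALSE
  data.frame(lncrna_id = lids, pcg_id = pids,
             distance = candidates$distance, pcc = pcc, p_value = p,
             undefined = undef, passes = passes,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally cis-target genes by transcription-factor family
#'
#' @param target_ids character vector of target gene ids.
#' @param tf_table data.frame with `gene_id` and `family` (PlantTFDB-style
#'   two-column table).
#' @return data.frame with `family` and `count`, decreasing by count; genes
#'   absent from the table contribute nothing.
#' @export
tf_family_tally <- function(target_ids, tf_table) {
  if (!all(c("gene_id", "family") %in% names(tf_table)))
    stopf("tf_family_tally: tf_table needs columns gene_id, family")
  fams <- tf_table$family[match(target_ids, tf_table$gene_id)]
  fams <- fams[!is.na(fams)]
  if (!length(fams))
    return(data.frame(family = character(0), count = integer(0)))
  tab <- sort(table(fams), decreasing = TRUE)
  data.frame(family = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Term depths from an OBO ontology file
#'
#' Minimal OBO parser: reads `[Term]` stanzas and `is_a` edges and returns
#' each term's depth (shortest path to a root, roots at depth 0).  Used for
#' optional GO-level slicing of enrichment results.
#'
#' @param path OBO-format file.
#' @return named integer vector of depths per term id.
#' @export
read_obo_depths <- function(path) {
  lines <- readLines(path)
  terms <- character(0); parents <- list()
  cur <- NA_character_
  for (ln in lines) {
    if (ln == "[Term]") { cur <- NA_character_; next }
    if (startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      terms <- c(terms, cur)
      parents[[cur]] <- character(0)
    } else if (startsWith(ln, "is_a: ") && !is.na(cur)) {
      p <- sub("^is_a: ", "", ln)
      p <- sub(" !.*$", "", p)
      parents[[cur]] <- c(parents[[cur]], trimws(p))
    }
  }
  depth <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  roots <- terms[lengths(parents[terms]) == 0]
  depth[roots] <- 0L
  # breadth-first relaxation
  frontier <- roots
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- terms[is.na(depth[terms]) &
                 vapply(parents[terms], function(p) any(p %in% frontier),
                        logical(1))]
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

#' Hypergeometric GO-term enrichment
#'
#' Upper-tail hypergeometric test per term with at least one study gene,
#' Benjamini-Hochberg adjusted across tested terms.  When an ontology depth
#' map is supplied, only terms at the requested level are tested; without
#' one, all annotated terms are tested.
#'
#' @param study_set character vector of study gene ids (must be a subset of
#'   the population).
#' @param population_set character vector of population gene ids.
#' @param annotation data.frame with `gene_id` and `term_id` (optionally
#'   `term_name`).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param term_depths optional named depth vector from [read_obo_depths()].
#' @param level optional term depth to slice at (used with `term_depths`).
#' @return data.frame with `term_id`, `term_name`, `study_count`,
#'   `study_size`, `population_count`, `population_size`, `p_value`,
#'   `adjusted_p`, `significant`.
#' @export
hypergeometric_enrichment <- function(study_set, population_set, annotation,
                                      alpha = 0.05, term_depths = NULL,
                                      level = NULL) {
  study_set <- unique(study_set)
  population_set <- unique(population_set)
  if (!all(study_set %in% population_set))
    stopf("hypergeometric_enrichment: study set is not a subset of the population")
  if (!is.null(term_depths) && !is.null(level))
    annotation <- annotation[
      annotation$term_id %in% names(term_depths)[term_depths == level], ,
      drop = FALSE]
  ann <- annotation[annotation$gene_id %in% population_set, , drop = FALSE]
  ann <- unique(ann[c("gene_id", "term_id",
                      intersect("term_name", names(ann)))])
  N <- length(population_set)
  n <- length(study_set)
  terms <- split(ann$gene_id, ann$term_id)
  rows <- list()
  for (tid in names(terms)) {
    genes <- unique(terms[[tid]])
    K <- length(genes)
    k <- length(intersect(genes, study_set))
    if (k == 0) next
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    nm <- if ("term_name" %in% names(ann))
      ann$term_name[match(tid, ann$term_id)] else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = tid, term_name = nm, study_count = k, study_size = n,
      population_count = K, population_size = N, p_value = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term_id = character(0), term_name = character(0),
                      study_count = integer(0), study_size = integer(0),
                      population_count = integer(0), population_size = integer(0),
                      p_value = numeric(0), adjusted_p = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
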