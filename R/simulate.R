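# Synthetic-data generator.  Produces a self-consistent toy genome
# annotation, assembled transcript models whose geometry forces known class
# codes, transcript sequences with controlled ORF content and GC, an FPKM
# matrix with planted differential expression, genotype-dependent presence,
# co-expression modules and cis-correlated pairs, auxiliary databases
# (known RNAs, miRNAs, GO, TF families), and a motif-conserved homolog
# family across pseudo-species.  Every planted positive passes its
# downstream screening predicate with margin; every planted negative fails
# exactly one predicate.  The seed fully determines every emitted file.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
.CODONS61 <- {
  all3 <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                          .BASES, paste0))
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}
.ORF_LIMIT <- 250L  # planted noncoding sequences keep ORFs below this

.rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(.BASES, n, replace = TRUE, prob = p)
}

# complete ORFs (ATG..stop) of at least min_len nt in a character vector;
# returns a data.frame of start (1-based) and length
.orf_spans <- function(chars, min_len = .ORF_LIMIT) {
  n <- length(chars)
  out <- list()
  if (n < min_len) return(data.frame(start = integer(0), len = integer(0)))
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    st <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- paste0(chars[st], chars[st + 1L], chars[st + 2L])
    is_start <- which(codons == "ATG")
    is_stop <- which(codons %in% .STOP_CODONS)
    if (!length(is_start) || !length(is_stop)) next
    for (i in is_start) {
      nxt <- is_stop[is_stop > i]
      if (!length(nxt)) break
      len <- (nxt[1] - i + 1L) * 3L
      if (len >= min_len)
        out[[length(out) + 1L]] <- c(st[i], len)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), len = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], len = m[, 2])
}

# break every complete ORF >= limit by stamping a stop cassette into an
# unprotected stretch near the middle of the ORF; returns the fixed
# character vector or NULL when an ORF cannot be broken.  The cassette
# carries a TAA in all three reading frames, so a break can never extend an
# ORF in another frame (a single in-frame TAA could overwrite that frame's
# stop and cycle).
.STOP_CASSETTE <- c("T", "A", "A", "G", "T", "A", "A", "G", "T", "A", "A")

.break_orfs <- function(chars, protected = NULL, limit = .ORF_LIMIT) {
  if (is.null(protected)) protected <- rep(FALSE, length(chars))
  n <- length(chars)
  cw <- length(.STOP_CASSETTE)
  for (iter in 1:80) {
    spans <- .orf_spans(chars, limit)
    if (!nrow(spans)) return(chars)
    sp <- spans[which.max(spans$len), ]
    ncod <- sp$len %/% 3L
    # candidate internal codon slots (skip ATG and the stop), middle first
    slots <- seq_len(ncod - 2L) + 1L
    slots <- slots[order(abs(slots - ncod / 2))]
    done <- FALSE
    for (t in slots) {            # all-frame cassette where it fits
      pos <- sp$start + 3L * (t - 1L)
      if (pos + cw - 1L <= n && !any(protected[pos:(pos + cw - 1L)])) {
        chars[pos:(pos + cw - 1L)] <- .STOP_CASSETTE
        done <- TRUE
        break
      }
    }
    if (!done) for (t in slots) { # fall back to a single in-frame stop
      pos <- sp$start + 3L * (t - 1L)
      if (!any(protected[pos:(pos + 2L)])) {
        chars[pos:(pos + 2L)] <- c("T", "A", "A")
        done <- TRUE
        break
      }
    }
    if (!done) return(NULL)
  }
  NULL
}

# genomic positions of a transcript in transcript (5'->3') order
.tx_gpos <- function(exons, strand) {
  gpos <- unlist(Map(seq.int, exons[, 1], exons[, 2]))
  if (strand == "-") rev(gpos) else gpos
}

# transcript sequence chars from a genome character vector
.tx_extract <- function(genome_chr, exons, strand) {
  gpos <- .tx_gpos(exons, strand)
  ch <- genome_chr[gpos]
  if (strand == "-") unname(.COMP[ch]) else ch
}

# stamp transcript chars into the genome character vector
.tx_stamp <- function(genome_chr, exons, strand, txchars) {
  gpos <- .tx_gpos(exons, strand)
  vals <- if (strand == "-") unname(.COMP[txchars]) else txchars
  genome_chr[gpos] <- vals
  genome_chr
}

# deferred stamping: per-chromosome accumulator of (positions, values),
# applied in one vector assignment per chromosome.  Stamping gene-by-gene
# would copy the whole chromosome vector on every call.
.stamp_acc <- function(chroms) {
  acc <- new.env(parent = emptyenv())
  acc$pos <- stats::setNames(vector("list", length(chroms)), chroms)
  acc$val <- stats::setNames(vector("list", length(chroms)), chroms)
  acc
}

.stamp_add <- function(acc, chr, exons, strand, txchars) {
  gpos <- .tx_gpos(exons, strand)
  vals <- if (strand == "-") unname(.COMP[txchars]) else txchars
  acc$pos[[chr]][[length(acc$pos[[chr]]) + 1L]] <- gpos
  acc$val[[chr]][[length(acc$val[[chr]]) + 1L]] <- vals
  invisible(acc)
}

.stamp_apply <- function(genome, acc) {
  for (chr in names(acc$pos)) {
    if (!length(acc$pos[[chr]])) next
    genome[[chr]][unlist(acc$pos[[chr]])] <- unlist(acc$val[[chr]])
  }
  genome
}

#' Generate the reference annotation and genome sequence
#'
#' Places protein-coding genes (multi-exon, with a complete planted ORF) and
#' reference noncoding genes along the chromosomes, reserving intergenic
#' slots for the assembled transcripts planted later: cis-pair slots at
#' controlled distances downstream of designated partner PCGs, one far slot
#' at a gap just beyond the cis window, generic slots for intergenic
#' transcripts, and at least one intergenic gap larger than 100 kb.
#'
#' @param config a [sim_config()].
#' @return list with `genes`, `tx` (reference transcript table), `tx_seq`,
#'   `coding` (named logical), `genome` (list of character vectors),
#'   `slots` (reserved intergenic slots), `cis_partners`.
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  chrom_len <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(n_chr))

  n_pcg <- config$n_pcg
  n_nc <- if (n_pcg == 0 && sum(config$n_lnc_per_class) == 0) 0L else config$n_ref_nc
  n_genes <- n_pcg + n_nc

  genome <- lapply(seq_len(n_chr), function(i) .rand_seq(chrom_len, gc = 0.436))
  names(genome) <- chroms

  if (n_genes == 0) {
    return(list(genes = data.frame(), tx = data.frame(
      transcript_id = character(0), gene_id = character(0),
      seqnames = character(0), strand = character(0),
      start = numeric(0), end = numeric(0)),
      tx_seq = character(0), coding = logical(0), genome = genome,
      slots = data.frame(), cis_partners = data.frame(),
      chroms = chroms))
  }

  # interleave noncoding reference genes among the PCGs
  types <- rep("PCG", n_genes)
  if (n_nc > 0) {
    nc_at <- unique(pmin(n_genes, round(seq(3, n_genes - 2, length.out = n_nc))))
    while (length(nc_at) < n_nc)  # de-duplicate collisions at tiny n_genes
      nc_at <- unique(c(nc_at, sample(setdiff(seq_len(n_genes), nc_at), 1)))
    types[nc_at] <- "ncRNA"
  }
  pcg_pos <- which(types == "PCG")

  # slot bookkeeping ---------------------------------------------------------
  n_u <- config$n_lnc_per_class[["u"]]
  n_cis <- min(config$cis_pair_count, max(0, n_u - 3))
  n_generic <- n_u - n_cis - 1L +               # generic u (one goes far)
    5L * config$n_neg_per_mode                  # short/known/coding/mirna/low
  n_generic <- max(n_generic, 0L)
  cis_distances <- if (n_cis > 0)
    round(seq(5000, 95000, length.out = n_cis)) else numeric(0)
  if (n_cis >= 1) cis_distances[1] <- 50000

  # PCG indices (within gene order) hosting a reserved downstream slot
  cis_host <- if (n_cis > 0)
    pcg_pos[round(seq(2, length(pcg_pos) - 2, length.out = n_cis))] else integer(0)
  far_host <- if (n_u >= 1 && length(pcg_pos) > n_cis + 4)
    setdiff(pcg_pos, cis_host)[5] else integer(0)

  # generic slots hang after evenly spaced genes (excluding reserved hosts)
  free_pos <- setdiff(seq_len(n_genes), c(cis_host, far_host))
  generic_host <- if (n_generic > 0)
    free_pos[unique(round(seq(1, length(free_pos), length.out = n_generic)))] else integer(0)
  if (length(generic_host) < n_generic)
    stopf("generator capacity: not enough genes to host %d intergenic slots",
          n_generic)
  biggap_host <- setdiff(free_pos, generic_host)[2]  # one plain >100 kb gap

  SLOT_LEN <- 2600

  # gene structures -----------------------------------------------------------
  genes <- vector("list", n_genes)
  tx_rows <- vector("list", n_genes)
  tx_seq <- character(n_genes)
  coding <- logical(n_genes)
  slots <- list()
  cis_partners <- list()

  stamps <- .stamp_acc(chroms)
  cursor <- stats::setNames(rep(1, n_chr), chroms)
  chr_of <- chroms[(seq_len(n_genes) - 1) %% n_chr + 1]
  ipcg <- 0L; inc <- 0L
  for (g in seq_len(n_genes)) {
    chr <- chr_of[g]
    gap <- sample(800:2500, 1)
    start <- cursor[chr] + gap
    strand <- sample(c("+", "-"), 1)
    if (types[g] == "PCG") {
      ipcg <- ipcg + 1L
      gid <- sprintf("PCG_%04d", ipcg)
      ne <- sample(2:5, 1)
      elen <- sample(250:450, ne, replace = TRUE)
      ilen <- if (ne > 1) sample(400:800, ne - 1, replace = TRUE) else integer(0)
      estart <- start + c(0, cumsum(elen[-ne] + ilen))
      eend <- estart + elen - 1
      L <- sum(elen)
      # coding sequence: 30 nt 5'UTR, ATG, non-stop codons, stop, 3'UTR
      k <- (L - 66L) %/% 3L
      seqc <- c(.rand_seq(30, 0.45), c("A", "T", "G"),
                strsplit(paste(sample(.CODONS61, k, replace = TRUE),
                               collapse = ""), "")[[1]],
                c("T", "G", "A"))
      seqc <- c(seqc, .rand_seq(L - length(seqc), 0.45))
      coding[g] <- TRUE
    } else {
      inc <- inc + 1L
      gid <- sprintf("NCG_%03d", inc)
      if (inc %% 3 == 0) {  # two-exon noncoding reference genes
        elen <- sample(200:350, 2, replace = TRUE)
        ilen <- sample(300:500, 1)
        estart <- start + c(0, elen[1] + ilen)
        eend <- estart + elen - 1
      } else {
        elen <- sample(300:700, 1)
        estart <- start; eend <- start + elen - 1
      }
      L <- sum(elen)
      seqc <- .break_orfs(.rand_seq(L, stats::runif(1, 0.3, 0.65)))
      coding[g] <- FALSE
    }
    gend <- max(eend)
    if (gend > chrom_len - 2000)
      stopf("generator capacity: %d genes do not fit on %d x %s nt chromosomes",
            n_genes, n_chr, format(chrom_len, scientific = FALSE))
    genes[[g]] <- data.frame(gene_id = gid, type = types[g], seqnames = chr,
                             strand = strand, start = start, end = gend,
                             stringsAsFactors = FALSE)
    tx_rows[[g]] <- data.frame(transcript_id = paste0(gid, ".1"), gene_id = gid,
                               seqnames = chr, strand = strand,
                               start = estart, end = eend,
                               stringsAsFactors = FALSE)
    tx_seq[g] <- paste(seqc, collapse = "")
    names(tx_seq)[g] <- paste0(gid, ".1")
    .stamp_add(stamps, chr, cbind(estart, eend), strand, seqc)
    cursor[chr] <- gend

    # reserved slot after this gene?
    if (g %in% cis_host) {
      d <- cis_distances[match(g, cis_host)]
      slots[[length(slots) + 1L]] <- data.frame(
        purpose = "cis", seqnames = chr, start = gend + d + 1,
        max_len = SLOT_LEN, partner_gene = gid, distance = d,
        stringsAsFactors = FALSE)
      cursor[chr] <- gend + d + SLOT_LEN
    } else if (g %in% far_host) {
      d <- 100001
      slots[[length(slots) + 1L]] <- data.frame(
        purpose = "far", seqnames = chr, start = gend + d + 1,
        max_len = SLOT_LEN, partner_gene = gid, distance = d,
        stringsAsFactors = FALSE)
      cursor[chr] <- gend + d + SLOT_LEN
    } else if (g %in% generic_host) {
      slots[[length(slots) + 1L]] <- data.frame(
        purpose = "generic", seqnames = chr, start = gend + 1200,
        max_len = SLOT_LEN, partner_gene = NA_character_, distance = NA_real_,
        stringsAsFactors = FALSE)
      cursor[chr] <- gend + 1200 + SLOT_LEN
    } else if (isTRUE(g == biggap_host)) {
      cursor[chr] <- gend + 120000   # a plain intergenic gap > 100 kb
    }
  }

  genome <- .stamp_apply(genome, stamps)
  genes <- do.call(rbind, genes)
  tx <- do.call(rbind, tx_rows)
  rownames(tx) <- NULL
  slots <- if (length(slots)) do.call(rbind, slots) else
    data.frame(purpose = character(0), seqnames = character(0),
               start = numeric(0), max_len = numeric(0),
               partner_gene = character(0), distance = numeric(0))
  list(genes = genes, tx = tx, tx_seq = tx_seq, coding = coding,
       genome = genome, slots = slots, chroms = chroms)
}
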