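# Planting of assembled transcript models (continued from simulate.R):
# geometry forcing each class code, sequence control (GC, ORF content,
# database hits), and the homolog family with planted motif architectures.

# choose n host PCGs satisfying a predicate, deterministically spread
.pick_hosts <- function(ok_idx, n, avoid = integer(0)) {
  pool <- setdiff(ok_idx, avoid)
  if (length(pool) < n)
    stopf("generator capacity: only %d suitable host genes for %d planted transcripts",
          length(pool), n)
  sel <- unique(pool[round(seq(1, length(pool), length.out = n))])
  if (length(sel) < n) sel <- c(sel, setdiff(pool, sel)[seq_len(n - length(sel))])
  sel
}

#' Generate assembled transcript models with planted class codes
#'
#' Plants, for each class code in u/x/i/o/j, transcripts whose geometry
#' forces that code, plus the six families of screening negatives (one per
#' failure mode: "=" chain identity, length <= 200, known-RNA hit, coding
#' ORF, miRNA-precursor hit, sub-threshold FPKM).  Sequences of planted
#' noncoding transcripts keep their longest complete ORF below 250 nt;
#' coding decoys carry an ORF >= 450 nt.  Returns the assembled transcript
#' table, sequences, the updated genome, truth annotations, and the
#' database entries (known-RNA / miRNA copies) that make the planted hits
#' real.
#'
#' @param config a [sim_config()].
#' @param ann output of [generate_annotation()].
#' @param family_seqs optional named character vector of rice homolog-family
#'   sequences to embed as intergenic lncRNAs.
#' @return list with `tx`, `tx_seq`, `truth`, `genome`, `known_extra`,
#'   `mirna_extra`.
#' @export
generate_transcript_models <- function(config, ann, family_seqs = NULL) {
  set.seed(config$seed + 1L)
  genome <- ann$genome
  genes <- ann$genes
  ref_tx <- ann$tx

  n_class <- config$n_lnc_per_class
  n_neg <- config$n_neg_per_mode
  n_u <- n_class[["u"]]

  slots <- ann$slots
  cis_slots <- which(slots$purpose == "cis")
  far_slot <- which(slots$purpose == "far")
  gen_slots <- which(slots$purpose == "generic")
  n_cis <- length(cis_slots)
  gi <- 0L  # generic slot cursor
  next_gen_slot <- function() {
    gi <<- gi + 1L
    if (gi > length(gen_slots)) stopf("generator capacity: out of intergenic slots")
    gen_slots[gi]
  }

  # reference exon mask per chromosome (protected positions)
  protected <- lapply(ann$genome, function(g) logical(length(g)))
  for (chr in unique(ref_tx$seqnames)) {
    rows <- ref_tx[ref_tx$seqnames == chr, ]
    protected[[chr]][unlist(Map(seq.int, rows$start, rows$end))] <- TRUE
  }
  is_protected <- function(chr, gpos) protected[[chr]][gpos]

  pcg_idx <- which(genes$type == "PCG")
  # per-gene structure lookup
  gene_tx <- split(seq_len(nrow(ref_tx)), ref_tx$gene_id)

  tid_n <- 0L
  new_ids <- function() {
    tid_n <<- tid_n + 1L
    c(sprintf("TCONS_%08d", tid_n), sprintf("XLOC_%06d", tid_n))
  }

  tx_rows <- list(); tx_seq <- character(0)
  stamps <- .stamp_acc(names(genome))
  truth <- list()
  known_extra <- character(0); mirna_extra <- character(0)
  used_hosts <- integer(0)

  # finalize one planted transcript: stamp, extract, ORF-control
  plant <- function(exons, strand, chr, role, class_planted, is_lnc,
                    failure_mode = NA_character_, newseq = NULL,
                    orf_free = TRUE, cis_partner = NA_character_,
                    cis_distance = NA_real_, keep_region = NULL) {
    ids <- new_ids()
    gpos <- .tx_gpos(exons, strand)
    prot <- is_protected(chr, gpos)            # in transcript order
    chars <- .tx_extract(genome[[chr]], exons, strand)
    if (!is.null(newseq)) {                    # overwrite unprotected positions
      chars[!prot] <- newseq[!prot]
    }
    prot2 <- prot
    if (!is.null(keep_region)) prot2[keep_region] <- TRUE
    if (orf_free) {
      fixed <- .break_orfs(chars, protected = prot2)
      if (is.null(fixed))
        stopf("generator: could not remove ORFs from planted transcript %s", ids[1])
      chars <- fixed
    }
    .stamp_add(stamps, chr, exons, strand, chars)
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      transcript_id = ids[1], gene_id = ids[2], seqnames = chr,
      strand = strand, start = exons[, 1], end = exons[, 2],
      stringsAsFactors = FALSE)
    s <- paste(chars, collapse = "")
    tx_seq[ids[1]] <<- s
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = ids[1], locus_id = ids[2], role = role,
      class_planted = class_planted, is_lncRNA = is_lnc,
      failure_mode = failure_mode, length = nchar(s),
      gc = gc_content(s), cis_partner = cis_partner,
      cis_distance = cis_distance, stringsAsFactors = FALSE)
    ids[1]
  }

  slot_exons <- function(si, len, two_exon = FALSE) {
    st <- slots$start[si]
    if (two_exon) {
      e1 <- round(len * 0.45)
      intron <- 250L
      rbind(c(st, st + e1 - 1), c(st + e1 + intron, st + len + intron - 1))
    } else rbind(c(st, st + len - 1))
  }

  # --- intergenic (u) positives --------------------------------------------
  fam_ids <- character(0)
  n_fam <- if (is.null(family_seqs)) 0L else length(family_seqs)
  act_ids <- list(sorbitol = character(0), NaCl = character(0))
  cis_records <- list()
  u_planted <- 0L
  for (ci in seq_len(n_cis)) {                    # cis-slot u lncRNAs
    si <- cis_slots[ci]
    len <- sample(800:1200, 1)
    ex <- slot_exons(si, len)
    tid <- plant(ex, sample(c("+", "-"), 1), slots$seqnames[si], "lnc_cis", "u",
                 TRUE, newseq = .rand_seq(len, stats::runif(1, 0.3, 0.65)),
                 cis_partner = paste0(slots$partner_gene[si], ".1"),
                 cis_distance = slots$distance[si])
    cis_records[[ci]] <- data.frame(
      lncrna_id = tid, pcg_id = paste0(slots$partner_gene[si], ".1"),
      distance = slots$distance[si], stringsAsFactors = FALSE)
    u_planted <- u_planted + 1L
  }
  if (length(far_slot)) {                         # just outside the window
    si <- far_slot[1]
    len <- 800L
    plant(slot_exons(si, len), "+", slots$seqnames[si], "lnc_far", "u", TRUE,
          newseq = .rand_seq(len, 0.5),
          cis_partner = paste0(slots$partner_gene[si], ".1"),
          cis_distance = slots$distance[si])
    u_planted <- u_planted + 1L
  }
  for (fi in seq_len(n_fam)) {                    # homolog-family members
    si <- next_gen_slot()
    fseq <- strsplit(family_seqs[[fi]], "")[[1]]
    tid <- plant(rbind(c(slots$start[si], slots$start[si] + length(fseq) - 1)),
                 "+", slots$seqnames[si], "lnc_family", "u", TRUE,
                 newseq = fseq, orf_free = FALSE)
    fam_ids <- c(fam_ids, tid)
    u_planted <- u_planted + 1L
  }
  n_act_sorb <- 3L; n_act_nacl <- 2L
  while (u_planted < n_u) {
    si <- next_gen_slot()
    two <- u_planted %% 4 == 3
    len <- sample(400:1500, 1)
    role <- "lnc_u"
    if (n_act_sorb > 0) { role <- "lnc_activated_sorbitol"; n_act_sorb <- n_act_sorb - 1L }
    else if (n_act_nacl > 0) { role <- "lnc_activated_NaCl"; n_act_nacl <- n_act_nacl - 1L }
    tid <- plant(slot_exons(si, len, two_exon = two), sample(c("+", "-"), 1),
                 slots$seqnames[si], role, "u", TRUE,
                 newseq = .rand_seq(len, stats::runif(1, 0.3, 0.65)))
    if (role == "lnc_activated_sorbitol") act_ids$sorbitol <- c(act_ids$sorbitol, tid)
    if (role == "lnc_activated_NaCl") act_ids$NaCl <- c(act_ids$NaCl, tid)
    u_planted <- u_planted + 1L
  }

  # --- antisense (x) and sense-overlap (o) positives ------------------------
  # hosts: PCGs whose downstream gap is free for a 250 nt extension
  gene_order <- order(genes$seqnames, genes$start)
  next_start <- rep(Inf, nrow(genes))
  for (chr in unique(genes$seqnames)) {
    idx <- gene_order[genes$seqnames[gene_order] == chr]
    next_start[idx[-length(idx)]] <- genes$start[idx[-1]]
  }
  slot_starts <- split(slots$start, slots$seqnames)
  free_after <- vapply(seq_len(nrow(genes)), function(g) {
    lim <- next_start[g]
    ss <- slot_starts[[genes$seqnames[g]]]
    ss <- ss[ss > genes$end[g]]
    if (length(ss)) lim <- min(lim, min(ss))
    lim - genes$end[g]
  }, numeric(1))
  ok_ext <- intersect(pcg_idx, which(free_after > 450))

  # plant against successive candidate hosts, skipping hosts whose protected
  # sequence context leaves an unbreakable ORF
  plant_hosted <- function(pool, n, builder) {
    planted <- 0L
    for (h in pool) {
      if (planted >= n) break
      ok <- tryCatch({ builder(h); TRUE },
                     error = function(e) {
                       if (grepl("could not remove ORFs", conditionMessage(e)))
                         FALSE else stop(e)
                     })
      if (ok) {
        used_hosts <<- c(used_hosts, h)
        planted <- planted + 1L
      }
    }
    if (planted < n)
      stopf("generator capacity: only %d of %d host transcripts plantable",
            planted, n)
  }

  for (cls in c("x", "o")) {
    pool <- .pick_hosts(ok_ext, min(length(setdiff(ok_ext, used_hosts)),
                                    4L * n_class[[cls]] + 4L),
                        avoid = used_hosts)
    plant_hosted(pool, n_class[[cls]], function(h) {
      hx <- ref_tx[gene_tx[[genes$gene_id[h]]], ]
      last_end <- max(hx$end)
      ex <- rbind(c(last_end - 149, last_end + 250))
      strand <- if (cls == "x") setdiff(c("+", "-"), genes$strand[h]) else
        genes$strand[h]
      plant(ex, strand, genes$seqnames[h], paste0("lnc_", cls), cls, TRUE,
            newseq = .rand_seq(400, stats::runif(1, 0.35, 0.6)))
    })
  }

  # --- intronic (i) positives ----------------------------------------------
  intron1_len <- vapply(seq_len(nrow(genes)), function(g) {
    hx <- ref_tx[gene_tx[[genes$gene_id[g]]], ]
    if (nrow(hx) < 2) return(0)
    hx <- hx[order(hx$start), ]
    hx$start[2] - hx$end[1] - 1
  }, numeric(1))
  i_ok <- intersect(pcg_idx, which(intron1_len >= 400))
  pool <- .pick_hosts(i_ok, min(length(setdiff(i_ok, used_hosts)),
                                4L * n_class[["i"]] + 4L), avoid = used_hosts)
  plant_hosted(pool, n_class[["i"]], function(h) {
    hx <- ref_tx[gene_tx[[genes$gene_id[h]]], ]
    hx <- hx[order(hx$start), ]
    st <- hx$end[1] + 31
    ex <- rbind(c(st, st + 319))
    plant(ex, genes$strand[h], genes$seqnames[h], "lnc_i", "i", TRUE,
          newseq = .rand_seq(320, stats::runif(1, 0.35, 0.6)))
  })

  # --- novel-isoform (j) positives ------------------------------------------
  n_exons_gene <- vapply(gene_tx[genes$gene_id], length, integer(1))
  prev_gap <- rep(Inf, nrow(genes))
  for (chr in unique(genes$seqnames)) {
    idx <- gene_order[genes$seqnames[gene_order] == chr]
    prev_gap[idx[-1]] <- genes$start[idx[-1]] - genes$end[idx[-length(idx)]]
  }
  j_ok <- intersect(pcg_idx, which(n_exons_gene >= 3 & prev_gap > 350))
  pool <- .pick_hosts(j_ok, min(length(setdiff(j_ok, used_hosts)),
                                6L * n_class[["j"]] + 4L), avoid = used_hosts)
  plant_hosted(pool, n_class[["j"]], function(h) {
    hx <- ref_tx[gene_tx[[genes$gene_id[h]]], ]
    hx <- hx[order(hx$start), ]
    ex <- rbind(c(hx$start[1] - 200, hx$end[1]),
                c(hx$start[2], hx$start[2] + 119))
    plant(ex, genes$strand[h], genes$seqnames[h], "lnc_j", "j", TRUE,
          newseq = .rand_seq(sum(ex[, 2] - ex[, 1] + 1),
                             stats::runif(1, 0.35, 0.6)))
  })

  # --- negatives -------------------------------------------------------------
  # (1) "=" decoys: copy reference noncoding transcript chains
  nc_idx <- which(genes$type == "ncRNA")
  if (length(nc_idx) < n_neg)
    stopf("generator capacity: need %d reference ncRNA genes for '=' decoys", n_neg)
  for (h in nc_idx[seq_len(n_neg)]) {
    hx <- ref_tx[gene_tx[[genes$gene_id[h]]], ]
    hx <- hx[order(hx$start), ]
    plant(cbind(hx$start, hx$end), genes$strand[h], genes$seqnames[h],
          "neg_class_eq", "=", FALSE, failure_mode = "class_code",
          orf_free = FALSE)  # copies an already noncoding reference sequence
  }
  # (2) short transcripts (length <= 200)
  for (k in seq_len(n_neg)) {
    si <- next_gen_slot()
    len <- if (k == 1) 200L else sample(150:200, 1)
    plant(slot_exons(si, len), "+", slots$seqnames[si], "neg_short", "u",
          FALSE, failure_mode = "length",
          newseq = .rand_seq(len, stats::runif(1, 0.3, 0.65)))
  }
  # (3) known-RNA hits: sequence copied into the known-RNA database
  for (k in seq_len(n_neg)) {
    si <- next_gen_slot()
    len <- 500L
    tid <- plant(slot_exons(si, len), "+", slots$seqnames[si], "neg_known",
                 "u", FALSE, failure_mode = "known_rna",
                 newseq = .rand_seq(len, stats::runif(1, 0.35, 0.6)))
    known_extra[sprintf("rRNA_synthetic_%02d", k)] <- tx_seq[[tid]]
  }
  # (4) coding ORF (>= 450 nt)
  for (k in seq_len(n_neg)) {
    si <- next_gen_slot()
    len <- 600L
    body <- .rand_seq(len, 0.5)
    orf <- c(c("A", "T", "G"),
             strsplit(paste(sample(.CODONS61, 148, replace = TRUE),
                            collapse = ""), "")[[1]], c("T", "G", "A"))
    body[61:(60 + length(orf))] <- orf
    plant(slot_exons(si, len), "+", slots$seqnames[si], "neg_coding", "u",
          FALSE, failure_mode = "coding", newseq = body, orf_free = FALSE)
  }
  # (5) miRNA-precursor hits
  for (k in seq_len(n_neg)) {
    si <- next_gen_slot()
    len <- 500L
    pre <- .break_orfs(.rand_seq(150, 0.5))
    body <- .rand_seq(len, 0.5)
    body[101:250] <- pre
    tid <- plant(slot_exons(si, len), "+", slots$seqnames[si], "neg_mirna",
                 "u", FALSE, failure_mode = "mirna",
                 newseq = body, keep_region = 101:250)
    mirna_extra[sprintf("osa-MIR-synthetic-%02d", k)] <- paste(pre, collapse = "")
  }
  # (6) sub-threshold FPKM
  for (k in seq_len(n_neg)) {
    si <- next_gen_slot()
    len <- 500L
    plant(slot_exons(si, len), "+", slots$seqnames[si], "neg_low_fpkm", "u",
          FALSE, failure_mode = "fpkm",
          newseq = .rand_seq(len, stats::runif(1, 0.3, 0.65)))
  }

  genome <- .stamp_apply(genome, stamps)
  tx <- do.call(rbind, tx_rows)
  rownames(tx) <- NULL
  truth <- do.call(rbind, truth)
  truth$stress_activated <- ifelse(
    truth$transcript_id %in% act_ids$sorbitol, "sorbitol",
    ifelse(truth$transcript_id %in% act_ids$NaCl, "NaCl", NA_character_))
  list(tx = tx, tx_seq = tx_seq, truth = truth, genome = genome,
       known_extra = known_extra, mirna_extra = mirna_extra,
       cis_pairs = if (length(cis_records)) do.call(rbind, cis_records) else
         data.frame(lncrna_id = character(0), pcg_id = character(0),
                    distance = numeric(0)),
       family_ids = fam_ids)
}

#' Generate the homolog family across pseudo-species
#'
#' Builds a lncRNA family sharing a mutated 300 nt backbone and three
#' conserved motifs, with two architectures: class 1 carries the motifs in
#' "312" order (5'->3') and class 2 in "213" order.  Some members are
#' emitted reverse-complemented and some carry a duplicated motif 2
#' (expansion).  One configured species is left without members.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (per species, named character vectors),
#'   `truth` (per-member table), `rice_members` (sequences planted into the
#'   rice genome as lncRNAs).
#' @export
generate_homolog_families <- function(config) {
  set.seed(config$seed + 2L)
  motifs <- config$motif_models
  if (!length(motifs)) stopf("generate_homolog_families: no motif models")
  backbone <- .break_orfs(.rand_seq(300, 0.45))

  mutate <- function(chars, rate = 0.02) {
    hit <- which(stats::runif(length(chars)) < rate)
    if (length(hit))
      chars[hit] <- sample(.BASES, length(hit), replace = TRUE)
    chars
  }
  mseq <- function(id) strsplit(motifs[[id]]$consensus, "")[[1]]

  build <- function(class_label, expand2 = FALSE) {
    order_ids <- if (class_label == "class1") c(3L, 1L, 2L) else c(2L, 1L, 3L)
    parts <- list(.rand_seq(40, 0.45))
    for (id in order_ids) {
      parts[[length(parts) + 1L]] <- mseq(id)
      if (id == 2L && expand2) {
        parts[[length(parts) + 1L]] <- .rand_seq(20, 0.45)
        parts[[length(parts) + 1L]] <- mseq(2L)
      }
      parts[[length(parts) + 1L]] <- .rand_seq(sample(30:60, 1), 0.45)
    }
    parts[[length(parts) + 1L]] <- mutate(backbone)
    parts[[length(parts) + 1L]] <- .rand_seq(40, 0.45)
    chars <- .break_orfs(unlist(parts))
    paste(chars, collapse = "")
  }

  # planted membership: species -> list of (class, revcomp, expansion)
  plan <- list(
    O_punctata = list(c("class1", FALSE, FALSE)),
    O_barthii = list(c("class1", FALSE, FALSE), c("class1", TRUE, FALSE)),
    O_rufipogon = list(c("class1", FALSE, FALSE), c("class2", FALSE, TRUE)),
    O_sativa = list(c("class2", FALSE, FALSE), c("class2", FALSE, TRUE),
                    c("class1", TRUE, FALSE))
  )
  plan <- plan[intersect(names(plan), config$species)]

  sequences <- list(); truth <- list(); rice <- character(0)
  for (sp in config$species) {
    members <- plan[[sp]]
    seqs <- character(0)
    for (i in seq_along(members)) {
      m <- members[[i]]
      cls <- m[1]; rc <- as.logical(m[2]); exp2 <- as.logical(m[3])
      s <- build(cls, exp2)
      if (rc) s <- revcomp_chr(s)
      id <- sprintf("%s_lnc_%02d", sp, i)
      seqs[id] <- s
      truth[[length(truth) + 1L]] <- data.frame(
        sequence_id = id, species = sp, class_label = cls,
        architecture = if (cls == "class1") "312" else "213",
        revcomp = rc, motif2_expanded = exp2, stringsAsFactors = FALSE)
      if (sp == "O_sativa" && !rc && length(rice) < 2)
        rice[id] <- s
    }
    sequences[[sp]] <- seqs
  }
  truth <- do.call(rbind, truth)
  list(sequences = sequences, truth = truth, rice_members = rice)
}
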