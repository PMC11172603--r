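# End-to-end synthetic dataset writer: runs the annotation, transcript,
# expression and homolog-family generators in a fixed seed order and writes
# every pipeline input plus the truth tables to an output directory.

.write_genome_fasta <- function(genome, path) {
  seqs <- vapply(genome, paste, character(1), collapse = "")
  write_fasta(seqs, path)
}

#' Generate and write the complete synthetic dataset
#'
#' Emits, under `out_dir`: `reference.gtf`, `assembled.gtf`, `genome.fa`,
#' `transcripts.fa`, `fpkm.tsv`, `design.tsv`, `known_rna.fa`, `mirna.fa`,
#' `go_annotation.tsv`, `tf_families.tsv`, `motifs.tsv`, `family.fa`,
#' `species/<sp>.fa`, `config.yaml` and `truth/truth_*.tsv`.  The truth
#' files are test fixtures, not pipeline inputs.  Identical configurations
#' (including the seed) produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory objects (`annotation`,
#'   `transcripts`, `expression`, `family`, `paths`).
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "species"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)

  fam <- generate_homolog_families(config)
  ann <- generate_annotation(config)
  tm <- generate_transcript_models(config, ann, fam$rice_members)

  # matrix rows: reference transcripts (PCG + noncoding) then assembled
  tx_info <- rbind(
    data.frame(transcript_id = names(ann$tx_seq),
               kind = ifelse(ann$coding, "pcg", "ref_nc"),
               role = ifelse(ann$coding, "pcg", "ref_nc"),
               is_lncRNA = FALSE, cis_partner = NA_character_,
               stress_activated = NA_character_, stringsAsFactors = FALSE),
    data.frame(transcript_id = tm$truth$transcript_id,
               kind = "assembled", role = tm$truth$role,
               is_lncRNA = tm$truth$is_lncRNA,
               cis_partner = tm$truth$cis_partner,
               stress_activated = tm$truth$stress_activated,
               stringsAsFactors = FALSE))
  expr <- generate_expression(config, tx_info)

  # auxiliary databases -------------------------------------------------------
  set.seed(config$seed + 5L)
  known <- character(0)
  for (k in seq_len(12))
    known[sprintf("tRNA_decoy_%02d", k)] <-
      paste(.rand_seq(sample(80:1500, 1), stats::runif(1, 0.4, 0.6)),
            collapse = "")
  known <- c(known, tm$known_extra)
  mirna <- character(0)
  for (k in seq_len(8))
    mirna[sprintf("osa-miR-decoy-%02d", k)] <-
      paste(.rand_seq(21, 0.5), collapse = "")
  mirna <- c(mirna, tm$mirna_extra)

  # GO annotation over PCG transcripts; one term enriched in module 1
  set.seed(config$seed + 6L)
  pcg_ids <- tx_info$transcript_id[tx_info$kind == "pcg"]
  terms <- sprintf("GO:%07d", seq_len(40))
  term_names <- c("response to salt stress", "response to osmotic stress",
                  sprintf("generic process %d", seq_len(38)))
  go_rows <- list()
  mod1 <- expr$truth$modules$transcript_id[expr$truth$modules$module == 1]
  for (g in pcg_ids) {
    k <- sample(1:4, 1)
    tset <- sample(terms[-1], k)
    if (g %in% mod1 && stats::runif(1) < 0.6) tset <- c(terms[1], tset)
    else if (stats::runif(1) < 0.05) tset <- c(terms[1], tset)
    go_rows[[length(go_rows) + 1L]] <- data.frame(
      gene_id = g, term_id = tset,
      term_name = term_names[match(tset, terms)],
      namespace = "biological_process", stringsAsFactors = FALSE)
  }
  go <- do.call(rbind, go_rows)

  # TF families over a subset of PCGs, cis partners first (the TF survey of
  # cis targets needs non-empty tallies)
  fams <- c("AP2", "B3", "bHLH", "bZIP", "C2H2", "C3H", "ERF", "FAR1",
            "GATA", "MIKC_MADS", "MYB", "NAC", "TCP", "WOX", "WRKY")
  tf_genes <- unique(c(utils::head(tm$cis_pairs$pcg_id, 5),
                       sample(pcg_ids, min(60, length(pcg_ids)))))
  tf <- data.frame(gene_id = tf_genes,
                   family = fams[(seq_along(tf_genes) - 1) %% length(fams) + 1],
                   stringsAsFactors = FALSE)

  # ortholog truth: every species with planted members shares the family
  # backbone with the rice queries
  n_query <- length(tm$family_ids)
  ortho_truth <- data.frame(
    species = config$species,
    expected_count = vapply(config$species, function(sp) {
      if (is.null(fam$sequences[[sp]]) || !length(fam$sequences[[sp]])) 0L
      else n_query
    }, integer(1)), stringsAsFactors = FALSE)

  # write ----------------------------------------------------------------------
  p <- function(...) file.path(out_dir, ...)
  write_gtf(ann$tx, p("reference.gtf"), source = "reference")
  write_gtf(tm$tx, p("assembled.gtf"), source = "assembly")
  .write_genome_fasta(tm$genome, p("genome.fa"))
  write_fasta(tm$tx_seq, p("transcripts.fa"))
  write_fpkm(round(expr$fpkm, 4), p("fpkm.tsv"))
  write_tsv(expr$design, p("design.tsv"))
  write_fasta(known, p("known_rna.fa"))
  write_fasta(mirna, p("mirna.fa"))
  write_tsv(go, p("go_annotation.tsv"))
  write_tsv(tf, p("tf_families.tsv"))
  write_tsv(data.frame(
    motif_id = vapply(config$motif_models, `[[`, integer(1), "motif_id"),
    consensus = vapply(config$motif_models, `[[`, character(1), "consensus"),
    max_mismatches = vapply(config$motif_models, `[[`, integer(1),
                            "max_mismatches")), p("motifs.tsv"))
  all_fam <- unlist(unname(fam$sequences))
  write_fasta(all_fam, p("family.fa"))
  for (sp in config$species) {
    seqs <- fam$sequences[[sp]]
    if (is.null(seqs)) seqs <- character(0)
    write_fasta(seqs, p("species", paste0(sp, ".fa")))
  }

  tr_tx <- tm$truth
  tr_tx$related_label <-
    expr$truth$relatedness$label[match(tr_tx$transcript_id,
                                       expr$truth$relatedness$transcript_id)]
  write_tsv(tr_tx, p("truth", "truth_transcripts.tsv"))
  write_tsv(expr$truth$de, p("truth", "truth_de.tsv"))
  write_tsv(expr$truth$relatedness, p("truth", "truth_relatedness.tsv"))
  write_tsv(expr$truth$modules[expr$truth$modules$module > 0, ],
            p("truth", "truth_modules.tsv"))
  write_tsv(tm$cis_pairs, p("truth", "truth_cis.tsv"))
  write_tsv(fam$truth, p("truth", "truth_architecture.tsv"))
  write_tsv(ortho_truth, p("truth", "truth_orthologs.tsv"))

  cfg_out <- unclass(config)
  cfg_out$n_lnc_per_class <- as.list(cfg_out$n_lnc_per_class)
  cfg_out$de_frac <- as.list(cfg_out$de_frac)
  yaml::write_yaml(cfg_out, p("config.yaml"))

  invisible(list(annotation = ann, transcripts = tm, expression = expr,
                 family = fam, config = config, out_dir = out_dir))
}
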