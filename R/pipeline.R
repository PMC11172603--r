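# End-to-end orchestration: classify -> screen -> DE / relatedness /
# partitions -> co-expression network -> cis targets / TF survey / GO
# enrichment -> conservation / motif architectures, with a machine-readable
# summary, a resolved-configuration copy and a timestamped run log.  All
# stages are deterministic, so rerunning with the same configuration
# reproduces every artifact byte-identically (the log differs only in its
# timestamps).

#' Pipeline configuration
#'
#' Paths to the pipeline inputs plus every stage threshold, at the
#' analysis defaults: class codes i/o/u/j/x, minimum length 201 nt,
#' known-RNA/miRNA similarity 1e-10 and 90% identity, domain e-value 1e-5,
#' FPKM floor 0.5, DE thresholds 0.5/0.05/0.05, MAD keep 10,000, scale-free
#' R^2 cutoff 0.85, minimum module size 50, merge cut height 0.25, kME 0.8,
#' hub cutoff 0.5, edge threshold 0.25, cis window 100 kb with PCC 0.9,
#' conservation e-value 1e-5, enrichment alpha 0.05.
#'
#' @param input_dir directory holding the dataset files (as written by
#'   [simulate_dataset()]); individual paths can be overridden.
#' @param ... overrides for any path or threshold field.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, ...) {
  cfg <- list(
    reference_gtf = NULL, assembled_gtf = NULL, transcripts_fa = NULL,
    known_rna_fa = NULL, mirna_fa = NULL, fpkm_tsv = NULL, design_tsv = NULL,
    go_tsv = NULL, tf_tsv = NULL, motifs_tsv = NULL, family_fa = NULL,
    species_dir = NULL,
    keep_codes = c("i", "o", "u", "j", "x"), min_length = 201,
    sim_max_e = 1e-10, sim_min_identity = 90, domain_max_e = 1e-5,
    orf_min = 300, fpkm_floor = 0.5,
    de_lfc = 0.5, de_p = 0.05, de_q = 0.05, de_pseudo = 0.25,
    mad_keep = 10000, r2_cutoff = 0.85, min_module_size = 50,
    merge_cut_height = 0.25, kme_cutoff = 0.8, hub_cutoff = 0.5,
    edge_threshold = 0.25,
    cis_window = 100000, cis_pcc = 0.9, cis_p = 0.05,
    conserve_max_e = 1e-5, enrich_alpha = 0.05,
    seed = 1L)
  if (!is.null(input_dir)) {
    f <- function(x) file.path(input_dir, x)
    cfg$reference_gtf <- f("reference.gtf"); cfg$assembled_gtf <- f("assembled.gtf")
    cfg$transcripts_fa <- f("transcripts.fa"); cfg$known_rna_fa <- f("known_rna.fa")
    cfg$mirna_fa <- f("mirna.fa"); cfg$fpkm_tsv <- f("fpkm.tsv")
    cfg$design_tsv <- f("design.tsv"); cfg$go_tsv <- f("go_annotation.tsv")
    cfg$tf_tsv <- f("tf_families.tsv"); cfg$motifs_tsv <- f("motifs.tsv")
    cfg$family_fa <- f("family.fa"); cfg$species_dir <- f("species")
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("pipeline_config: unknown field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

.log_line <- function(con, stage, msg) {
  writeLines(sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     stage, msg), con)
}

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stopf("pipeline: missing %s file: %s", what, path %||% "<unset>")
  path
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for stage artifacts, `summary.json`,
#'   `summary.tsv`, `config_resolved.yaml` and `run.log`.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  step <- function(stage, expr) {
    .log_line(logf, stage, "start")
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    .log_line(logf, stage, "done")
    res
  }
  p <- function(...) file.path(out_dir, ...)
  summary <- list(package_version = as.character(utils::packageVersion("stresslnc")),
                  seed = config$seed)

  cfg_out <- unclass(config)
  yaml::write_yaml(cfg_out, p("config_resolved.yaml"))
  summary$config_hash <- unname(tools::md5sum(p("config_resolved.yaml")))

  # ---- inputs ---------------------------------------------------------------
  ref <- step("read", {
    read_gtf(.need_file(config$reference_gtf, "reference GTF"))
  })
  asm <- read_gtf(.need_file(config$assembled_gtf, "assembled GTF"))
  seqs <- read_fasta(.need_file(config$transcripts_fa, "transcript FASTA"))
  known <- read_fasta(.need_file(config$known_rna_fa, "known-RNA FASTA"))
  mirna <- read_fasta(.need_file(config$mirna_fa, "miRNA FASTA"))
  fpkm <- read_fpkm(.need_file(config$fpkm_tsv, "FPKM"))
  design <- read_design(.need_file(config$design_tsv, "design"))

  # ---- classification -------------------------------------------------------
  codes <- step("classify", compare_annotations(asm, ref))
  write_tsv(codes, p("class_codes.tsv"))

  # ---- screening ------------------------------------------------------------
  locus <- stats::setNames(asm$gene_id[!duplicated(asm$transcript_id)],
                           asm$transcript_id[!duplicated(asm$transcript_id)])
  rep <- step("filter", run_screening_pipeline(
    codes, seqs, known, mirna, fpkm,
    keep_codes = config$keep_codes, min_length = config$min_length,
    sim_max_e = config$sim_max_e, sim_min_identity = config$sim_min_identity,
    orf_min = config$orf_min, fpkm_floor = config$fpkm_floor,
    locus_ids = locus))
  write_tsv(rep$stages, p("screening_stages.tsv"))
  write_tsv(data.frame(transcript_id = names(rep$eliminated),
                       stage = unname(rep$eliminated)),
            p("screening_eliminated.tsv"))
  feats <- lncrna_features(rep, asm)
  write_tsv(feats, p("accepted_features.tsv"))
  accepted <- rep$accepted
  write_gtf(asm[asm$transcript_id %in% accepted, ], p("accepted.gtf"))
  write_fasta(seqs[accepted], p("accepted.fa"))
  summary$screening <- list(stages = rep$stages,
                            accepted = length(accepted),
                            accepted_loci = length(unique(feats$locus_id)),
                            mean_length = mean(feats$length),
                            mean_gc = mean(feats$gc),
                            class_counts = as.list(table(feats$class_code)))

  # ---- differential expression ---------------------------------------------
  genotypes <- unique(design$genotype)
  tissues <- unique(design$tissue)
  treatments <- setdiff(unique(design$treatment), "control")
  de <- list()
  step("de", for (g in genotypes) for (ts in tissues) for (tr in treatments) {
    key <- paste(g, ts, tr, sep = ":")
    de[[key]] <- differential_expression(
      fpkm, design, g, ts, tr, lfc_min = config$de_lfc,
      p_max = config$de_p, q_max = config$de_q, pseudo = config$de_pseudo)
    write_tsv(de[[key]], p(sprintf("de_%s_%s_%s.tsv", g, ts, tr)))
  })
  summary$de_counts <- lapply(de, function(d) {
    lnc <- d$transcript_id %in% accepted
    list(lncRNA = sum(d$significant & lnc),
         lncRNA_up = sum(d$significant & lnc & d$direction == "up"),
         PCG = sum(d$significant & !lnc))
  })

  rel <- step("relatedness", classify_relatedness(fpkm, design,
                                                  config$fpkm_floor))
  write_tsv(rel, p("relatedness.tsv"))
  summary$relatedness <- list(
    lncRNA = as.list(table(rel$label[rel$transcript_id %in% accepted])),
    all = as.list(table(rel$label)))

  parts <- list()
  step("partition", for (g in genotypes) for (ts in tissues) {
    key <- paste(g, ts, sep = ":")
    parts[[key]] <- partition_response(de[[paste(g, ts, "NaCl", sep = ":")]],
                                       de[[paste(g, ts, "sorbitol", sep = ":")]],
                                       ts)
    write_tsv(parts[[key]], p(sprintf("partition_%s_%s.tsv", g, ts)))
  })
  summary$partitions <- lapply(parts, function(x) as.list(table(x$category)))

  # relatedness x DE combination, both Boolean variants flagged by column
  step("related_responsive", for (ts in tissues) for (tr in treatments) {
    rsr <- related_stress_responsive(
      rel, de[[paste("WT", ts, tr, sep = ":")]],
      de[[paste(setdiff(genotypes, "WT")[1], ts, tr, sep = ":")]])
    write_tsv(rsr, p(sprintf("related_responsive_%s_%s.tsv", ts, tr)))
  })

  # group-level expression comparisons between genotypes and gene classes
  summary$group_tests <- step("group_tests", {
    lnc_rows <- rownames(fpkm) %in% accepted
    nonrel <- rel$transcript_id[rel$label == "non-related"]
    wt_cols <- design$sample_id[design$genotype == "WT"]
    mut_cols <- design$sample_id[design$genotype != "WT"]
    lnc_nonrel <- intersect(nonrel, rownames(fpkm)[lnc_rows])
    out <- list()
    if (length(lnc_nonrel) > 3) {
      a <- rowMeans(log2(fpkm[lnc_nonrel, wt_cols, drop = FALSE] + 1))
      b <- rowMeans(log2(fpkm[lnc_nonrel, mut_cols, drop = FALSE] + 1))
      if (!all(a == b))
        out$nonrelated_lnc_wt_vs_mut_wilcoxon_p <- group_comparison(
          a, b, test = "wilcoxon-signed-rank")$p_value
    }
    lnc_mean <- rowMeans(log2(fpkm[lnc_rows, , drop = FALSE] + 1))
    pcg_mean <- rowMeans(log2(fpkm[rownames(fpkm) %in% ref$transcript_id, ,
                                   drop = FALSE] + 1))
    out$lnc_vs_pcg_mannwhitney_p <- group_comparison(
      lnc_mean, pcg_mean, test = "mann-whitney")$p_value
    out
  })

  activated <- list()
  step("stress_activated", for (g in genotypes) for (tr in treatments) {
    key <- paste(g, tr, sep = ":")
    shoot <- de[[paste(g, "shoot", tr, sep = ":")]]
    root <- de[[paste(g, "root", tr, sep = ":")]]
    activated[[key]] <- intersect(find_stress_activated(shoot, root), accepted)
  })
  summary$stress_activated <- activated

  # ---- co-expression network -----------------------------------------------
  net_ids <- c(rownames(fpkm)[rownames(fpkm) %in% ref$transcript_id |
                              rownames(fpkm) %in% accepted])
  net <- step("network", {
    m <- mad_filter(fpkm[net_ids, , drop = FALSE], n_keep = config$mad_keep)
    lm <- log2(m + 1)
    sp <- pick_soft_power(lm, r2_cutoff = config$r2_cutoff)
    mods <- blockwise_modules(lm, sp$power,
                              min_module_size = config$min_module_size,
                              merge_cut_height = config$merge_cut_height,
                              kme_cutoff = config$kme_cutoff)
    list(expr = lm, soft = sp, tom = mods$tom, mods = mods)
  })
  mods <- net$mods
  write_tsv(data.frame(transcript_id = names(mods$labels),
                       module = unname(mods$labels)), p("modules.tsv"))
  summary$network <- list(soft_power = net$soft$power,
                          scale_free_r2 = net$soft$r2,
                          below_cutoff = net$soft$below_cutoff,
                          n_modules = length(unique(mods$labels[mods$labels > 0])),
                          module_sizes = as.list(table(mods$labels[mods$labels > 0])))
  if (!is.null(mods$eigengenes)) {
    write_tsv(data.frame(module = rownames(mods$eigengenes), mods$eigengenes,
                         check.names = FALSE), p("eigengenes.tsv"))
    cellv <- paste(design$genotype, design$tissue, design$treatment, sep = ".")
    traits <- t(vapply(unique(cellv), function(cv) as.numeric(cellv == cv),
                       numeric(nrow(design))))
    rownames(traits) <- unique(cellv)
    colnames(traits) <- design$sample_id
    mt <- module_trait_correlation(mods$eigengenes, traits)
    write_tsv(data.frame(module = rownames(mt$cor), mt$cor,
                         check.names = FALSE), p("module_trait_cor.tsv"))
    hubs <- find_hubs(mods$labels, mods$kme, net$expr, traits,
                      mods$eigengenes, cutoff = config$hub_cutoff)
    hubs$type <- ifelse(hubs$gene_id %in% accepted, "lncRNA", "PCG")
    write_tsv(hubs, p("hubs.tsv"))
    best <- which.max(apply(abs(mt$cor), 1, max))
    best_mod <- as.integer(sub("ME", "", rownames(mt$cor)[best]))
    node_type <- stats::setNames(
      ifelse(names(mods$labels) %in% accepted, "lncRNA", "PCG"),
      names(mods$labels))
    wts <- net$tom
    if (is.null(wts)) {  # blockwise run: recompute TOM on the module only
      members <- names(mods$labels)[mods$labels == best_mod]
      wts <- tom_similarity(adjacency_matrix(
        net$expr[members, , drop = FALSE], net$soft$power))
    }
    edges <- export_edges(wts, mods$labels[rownames(wts)], best_mod,
                          config$edge_threshold, node_type)
    write_tsv(edges, p("edges.tsv"))
    summary$network$best_module <- best_mod
    summary$network$best_module_trait <- colnames(mt$cor)[
      which.max(abs(mt$cor[best, ]))]
    summary$network$best_module_trait_r <- max(abs(mt$cor[best, ]), na.rm = TRUE)
    summary$network$hub_counts <- as.list(table(hubs$type[hubs$hub]))
    summary$network$edges_exported <- nrow(edges)
  }

  # ---- cis targets / TF survey / GO enrichment ------------------------------
  lnc_tx <- asm[asm$transcript_id %in% accepted, ]
  cis <- step("cis", {
    cands <- window_neighbors(lnc_tx, ref, window = config$cis_window)
    # map locus ids to matrix rows (first transcript of each gene)
    lmap <- stats::setNames(lnc_tx$transcript_id[!duplicated(lnc_tx$gene_id)],
                            lnc_tx$gene_id[!duplicated(lnc_tx$gene_id)])
    pmap <- stats::setNames(ref$transcript_id[!duplicated(ref$gene_id)],
                            ref$gene_id[!duplicated(ref$gene_id)])
    cis_pairs(cands, fpkm, lnc_map = lmap, pcg_map = pmap,
              pcc_min = config$cis_pcc, p_max = config$cis_p)
  })
  write_tsv(cis, p("cis_pairs.tsv"))
  targets <- unique(cis$pcg_id[cis$passes])
  tally <- step("tf", {
    tf_table <- read_tsv(.need_file(config$tf_tsv, "TF table"))
    tf_family_tally(targets, tf_table)
  })
  write_tsv(tally, p("tf_tally.tsv"))
  enrich <- step("enrich", {
    go <- read_tsv(.need_file(config$go_tsv, "GO annotation"))
    population <- unique(go$gene_id)
    hypergeometric_enrichment(intersect(targets, population), population, go,
                              alpha = config$enrich_alpha)
  })
  write_tsv(enrich, p("enrichment.tsv"))
  summary$cis <- list(candidates = nrow(cis), passing = sum(cis$passes),
                      target_genes = length(targets),
                      tf_families = nrow(tally),
                      tf_genes = sum(tally$count),
                      top_term = if (nrow(enrich)) enrich$term_id[1] else NA)

  # ---- conservation / motif architecture ------------------------------------
  ortho <- step("conserve", {
    spf <- list.files(config$species_dir, pattern = "\\.fa$", full.names = TRUE)
    sets <- lapply(spf, read_fasta)
    names(sets) <- sub("\\.fa$", "", basename(spf))
    suppressWarnings(count_orthologs(seqs[accepted], sets,
                                     max_e = config$conserve_max_e))
  })
  write_tsv(data.frame(species = names(ortho), count = as.integer(ortho)),
            p("ortholog_counts.tsv"))
  arch <- step("motifs", {
    motifs <- read_motif_tsv(.need_file(config$motifs_tsv, "motif models"))
    classify_family_architectures(read_fasta(.need_file(config$family_fa,
                                                        "family FASTA")),
                                  motifs)
  })
  write_tsv(arch, p("architectures.tsv"))
  summary$conservation <- list(ortholog_counts = as.list(ortho),
                               architecture_classes = as.list(table(arch$class_label)))

  # ---- summary --------------------------------------------------------------
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  flat <- data.frame(
    key = c("accepted_lncrnas", "accepted_loci", "n_modules", "cis_passing",
            "tf_families"),
    value = c(summary$screening$accepted, summary$screening$accepted_loci,
              summary$network$n_modules, summary$cis$passing,
              summary$cis$tf_families))
  write_tsv(flat, p("summary.tsv"))
  .log_line(logf, "pipeline", "complete")
  invisible(summary)
}
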