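# Simulation configuration for the synthetic-data generator.  The defaults
# define the study conditions the generator emulates: the 24-sample
# genotype x tissue x treatment x replicate design, a two-chromosome toy
# genome carrying ~2,600 protein-coding genes, 50 planted lncRNAs (one set
# per class code), 90 planted negatives (15 per screening failure mode),
# four co-expression modules of 100 genes (one tied to the root-sorbitol
# condition), ten cis pairs within 100 kb, and a motif-conserved homolog
# family across four Oryza-like pseudo-species.

.DEFAULT_MOTIFS <- list(
  list(motif_id = 1L, consensus = "TGACCGTTGAGC", max_mismatches = 1L),
  list(motif_id = 2L, consensus = "ACCGTAGGCTAA", max_mismatches = 1L),
  list(motif_id = 3L, consensus = "GGTCAATCGCAT", max_mismatches = 1L)
)

#' Simulation configuration
#'
#' @param seed integer seed; fully determines every emitted file.
#' @param n_chromosomes,chrom_length genome scale (nt per chromosome).
#' @param n_pcg number of protein-coding genes.
#' @param n_ref_nc number of reference noncoding genes (class "=" decoys
#'   copy these).
#' @param n_lnc_per_class planted lncRNAs per class code (named vector over
#'   u/x/i/o/j).
#' @param n_neg_per_mode planted negatives per screening failure mode
#'   (modes: class_eq, short, known_hit, coding, mirna_hit, low_fpkm).
#' @param genotypes,tissues,treatments,n_replicates the sample design
#'   (default 2 x 2 x 3 x 2 = 24 samples).
#' @param effect_log2fc planted treatment effect (log2).
#' @param activated_log2fc planted effect for stress-activated lncRNAs.
#' @param noise_cv coefficient of variation of FPKM across replicates.
#' @param n_modules,module_size planted co-expression modules (module 1 is
#'   tied to the root-sorbitol condition indicator).
#' @param cis_pair_count planted cis lncRNA-PCG pairs within 100 kb.
#' @param de_frac planted DE fraction per tissue x treatment contrast.
#' @param related_frac_lnc,related_frac_pcg fraction of lncRNAs / PCGs whose
#'   presence depends on genotype.
#' @param motif_models list of motif models for the homolog family.
#' @param architecture_classes planted 5'->3' motif orderings.
#' @param species pseudo-species carrying homolog-family members (the last
#'   one is intentionally empty).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 7.5e6,
                       n_pcg = 2600L,
                       n_ref_nc = 18L,
                       n_lnc_per_class = c(u = 30L, x = 8L, i = 6L, o = 4L, j = 2L),
                       n_neg_per_mode = 15L,
                       genotypes = c("WT", "ososca1.1"),
                       tissues = c("shoot", "root"),
                       treatments = c("control", "NaCl", "sorbitol"),
                       n_replicates = 2L,
                       effect_log2fc = 4,
                       activated_log2fc = 6,
                       noise_cv = 0.1,
                       n_modules = 4L,
                       module_size = 100L,
                       cis_pair_count = 10L,
                       de_frac = c(root_sorbitol = 0.12, root_NaCl = 0.05,
                                   shoot_sorbitol = 0.08, shoot_NaCl = 0.05),
                       related_frac_lnc = 0.5,
                       related_frac_pcg = 0.1,
                       motif_models = .DEFAULT_MOTIFS,
                       architecture_classes = c("312", "213"),
                       species = c("O_sativa", "O_rufipogon", "O_punctata",
                                   "O_barthii", "O_meridionalis")) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length), n_pcg = as.integer(n_pcg),
              n_ref_nc = as.integer(n_ref_nc),
              n_lnc_per_class = n_lnc_per_class,
              n_neg_per_mode = as.integer(n_neg_per_mode),
              genotypes = genotypes, tissues = tissues, treatments = treatments,
              n_replicates = as.integer(n_replicates),
              effect_log2fc = effect_log2fc,
              activated_log2fc = activated_log2fc,
              noise_cv = noise_cv, n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              cis_pair_count = as.integer(cis_pair_count),
              de_frac = de_frac,
              related_frac_lnc = related_frac_lnc,
              related_frac_pcg = related_frac_pcg,
              motif_models = motif_models,
              architecture_classes = architecture_classes,
              species = species)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic rice-seedling dataset configuration\n")
  cat(sprintf("  seed %d | %d chromosome(s) x %s nt | %d PCGs\n",
              x$seed, x$n_chromosomes, format(x$chrom_length, big.mark = ","),
              x$n_pcg))
  cat(sprintf("  planted lncRNAs: %s (total %d); negatives: %d x 6 modes\n",
              paste(sprintf("%s=%d", names(x$n_lnc_per_class),
                            x$n_lnc_per_class), collapse = " "),
              sum(x$n_lnc_per_class), x$n_neg_per_mode))
  cat(sprintf("  design: %d x %d x %d x %d = %d samples | noise CV %.2f | effect %.1f log2\n",
              length(x$genotypes), length(x$tissues), length(x$treatments),
              x$n_replicates,
              length(x$genotypes) * length(x$tissues) * length(x$treatments) *
                x$n_replicates, x$noise_cv, x$effect_log2fc))
  cat(sprintf("  modules: %d x %d genes | cis pairs: %d\n",
              x$n_modules, x$module_size, x$cis_pair_count))
  invisible(x)
}
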