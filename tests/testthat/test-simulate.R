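# Synthetic-data generator: determinism, planted-truth consistency, margins
# and degenerate configurations.

test_that("the same seed reproduces every emitted file byte-identically", {
  cfg <- sim_config(seed = 77, n_pcg = 120L, chrom_length = 1.3e6)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  m1 <- dir_md5(d1); m2 <- dir_md5(d2)
  expect_equal(names(m1), names(m2))
  expect_equal(unname(m1), unname(m2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty configuration yields an empty annotation but a valid genome", {
  cfg <- sim_config(seed = 1, n_pcg = 0L,
                    n_lnc_per_class = c(u = 0L, x = 0L, i = 0L, o = 0L, j = 0L),
                    chrom_length = 50000)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$tx), 0)
  expect_equal(length(ann$genome), 2)
  expect_true(all(nchar(unlist(ann$genome)) == 1))  # per-position characters
  expect_equal(length(ann$genome[["chr1"]]), 50000)
})

test_that("infeasible gene placement raises a capacity error", {
  cfg <- sim_config(seed = 1, n_pcg = 200L, chrom_length = 50000)
  expect_error(generate_annotation(cfg), "capacity")
})

test_that("planted cis distances are recoverable from the emitted coordinates", {
  sd <- small_dataset()
  truth <- read_tsv(file.path(sd$dir, "truth", "truth_cis.tsv"))
  expect_true(50000 %in% truth$distance)
  asm <- read_gtf(file.path(sd$dir, "assembled.gtf"))
  ref <- read_gtf(file.path(sd$dir, "reference.gtf"))
  for (i in seq_len(nrow(truth))) {
    lx <- asm[asm$transcript_id == truth$lncrna_id[i], ]
    px <- ref[ref$transcript_id == truth$pcg_id[i], ]
    gap <- max(min(lx$start), min(px$start)) -
           min(max(lx$end), max(px$end)) - 1
    expect_equal(max(0, gap), truth$distance[i])
  }
})

test_that("zero replicate noise makes replicates identical within condition", {
  cfg <- sim_config(seed = 9, noise_cv = 0)
  design <- sim_design(cfg)
  info <- data.frame(
    transcript_id = sprintf("t%03d", 1:50),
    kind = rep(c("pcg", "assembled"), 25),
    role = rep(c("pcg", "lnc_u"), 25),
    is_lncRNA = rep(c(FALSE, TRUE), 25),
    cis_partner = NA_character_, stress_activated = NA_character_,
    stringsAsFactors = FALSE)
  ex <- generate_expression(cfg, info)
  cellv <- paste(ex$design$genotype, ex$design$tissue, ex$design$treatment)
  for (cv in unique(cellv)) {
    cols <- which(cellv == cv)
    expect_equal(ex$fpkm[, cols[1]], ex$fpkm[, cols[2]])
  }
})

test_that("planted margins hold: positives detectable, negatives fail exactly one predicate", {
  sd <- small_dataset()
  truth <- small_truth()
  fpkm <- read_fpkm(file.path(sd$dir, "fpkm.tsv"))
  seqs <- read_fasta(file.path(sd$dir, "transcripts.fa"))
  pos <- truth[truth$is_lncRNA %in% c(TRUE, "TRUE"), ]
  # length >= 300, ORF below the coding threshold, max FPKM >= 1
  expect_true(all(pos$length >= 300))
  orfs <- vapply(pos$transcript_id, function(i) longest_orf(seqs[[i]]),
                 integer(1))
  expect_true(all(orfs < 300))
  expect_true(all(apply(fpkm[pos$transcript_id, ], 1, max) >= 1))
  # negatives: short ones fail only length; low-FPKM ones only expression
  neg <- truth[!truth$is_lncRNA %in% c(TRUE, "TRUE"), ]
  short <- neg[neg$failure_mode == "length", ]
  expect_true(all(short$length <= 200))
  expect_true(200 %in% short$length)
  low <- neg[neg$failure_mode == "fpkm", ]
  expect_true(all(apply(fpkm[low$transcript_id, ], 1, max) < 0.5))
  expect_true(all(low$length >= 300))
  coding <- neg[neg$failure_mode == "coding", ]
  orfs_c <- vapply(coding$transcript_id, function(i) longest_orf(seqs[[i]]),
                   integer(1))
  expect_true(all(orfs_c >= 300))
})

test_that("planted relatedness shows as genotype-dependent presence at 0.5 FPKM", {
  sd <- small_dataset()
  fpkm <- read_fpkm(file.path(sd$dir, "fpkm.tsv"))
  design <- read_design(file.path(sd$dir, "design.tsv"))
  rel_truth <- read_tsv(file.path(sd$dir, "truth", "truth_relatedness.tsv"))
  rel <- classify_relatedness(fpkm, design)
  m <- merge(rel, rel_truth, by = "transcript_id")
  expect_equal(m$label.x, m$label.y)
})

test_that("module blocks share their latent: near-unit correlation at low noise", {
  cfg <- sim_config(seed = 13, n_modules = 2L, module_size = 15L,
                    noise_cv = 0)
  sim <- simulate_module_matrix(cfg)
  lm <- log2(sim$fpkm)  # log-scale profiles are affine in the shared latent
  for (mod in 1:2) {
    block <- lm[sim$labels == mod, ]
    cc <- cor(t(block))
    expect_true(all(abs(cc) > 1 - 1e-10))
  }
})

test_that("homolog family truth round-trips through its own generator", {
  cfg <- sim_config(seed = 55)
  fam <- generate_homolog_families(cfg)
  expect_gte(length(fam$sequences), 4)
  expect_equal(length(fam$rice_members), 2)
  # reverse-complemented members keep their class label in truth
  expect_true(any(fam$truth$revcomp))
  # every listed sequence exists
  all_ids <- unlist(lapply(fam$sequences, names))
  expect_setequal(fam$truth$sequence_id, all_ids)
})
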