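# Screening pipeline: stage order, first-failure attribution, boundary
# conventions and stage-disabling monotonicity.

# a self-contained miniature screening instance
mini_instance <- function() {
  seqs <- c(
    ok = paste(rep("ACT", 150), collapse = ""),          # 450 nt, no ATG
    eq = paste(rep("ACT", 150), collapse = ""),
    short = strrep("ACTG", 50),                          # exactly 200 nt
    len201 = paste0(strrep("ACTG", 50), "C"),            # 201 nt survives
    coding = paste0(strrep("AC", 40),
                    "ATG", strrep("GCT", 120), "TGA",
                    strrep("AC", 40)),
    low = paste(rep("TCA", 150), collapse = ""))
  codes <- data.frame(
    transcript_id = names(seqs),
    class_code = c("u", "=", "u", "u", "u", "u"),
    matched_reference_id = NA, stringsAsFactors = FALSE)
  fpkm <- matrix(2, length(seqs), 4,
                 dimnames = list(names(seqs), sprintf("s%d", 1:4)))
  fpkm["low", ] <- c(0.4, 0.3, 0.2, 0.1)
  known <- c(known1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                            collapse = ""))
  mirna <- c(mir1 = paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                          collapse = ""))
  list(codes = codes, seqs = seqs, known = known, mirna = mirna, fpkm = fpkm)
}

test_that("stage order and boundary conventions: '=' first, 200 nt out, 201 in, 0.5 FPKM in", {
  set.seed(40)
  mi <- mini_instance()
  rep <- run_screening_pipeline(mi$codes, mi$seqs, mi$known, mi$mirna, mi$fpkm)
  expect_setequal(rep$accepted, c("ok", "len201"))
  expect_equal(unname(rep$eliminated["eq"]), "class_code")
  expect_equal(unname(rep$eliminated["short"]), "length")
  expect_equal(unname(rep$eliminated["coding"]), "coding")
  expect_equal(unname(rep$eliminated["low"]), "fpkm")
  # a row whose max is exactly 0.5 survives the floor (inclusive)
  fp <- mi$fpkm; fp["low", ] <- c(0.5, 0.1, 0.1, 0.1)
  rep2 <- run_screening_pipeline(mi$codes, mi$seqs, mi$known, mi$mirna, fp)
  expect_true("low" %in% rep2$accepted)
  # threshold 0 makes the floor vacuous
  expect_equal(expression_floor(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"), NULL)),
                                threshold = 0), c("a", "b"))
  expect_error(expression_floor(mi$fpkm, c("ok", "ghost")), "ghost")
})

test_that("stage counts are monotone and eliminations sum to input minus accepted", {
  sd <- small_dataset()
  d <- sd$dir
  codes <- compare_annotations(read_gtf(file.path(d, "assembled.gtf")),
                               read_gtf(file.path(d, "reference.gtf")))
  seqs <- read_fasta(file.path(d, "transcripts.fa"))
  known <- read_fasta(file.path(d, "known_rna.fa"))
  mirna <- read_fasta(file.path(d, "mirna.fa"))
  fpkm <- read_fpkm(file.path(d, "fpkm.tsv"))
  rep <- run_screening_pipeline(codes, seqs, known, mirna, fpkm)
  expect_true(all(diff(rep$stages$surviving) <= 0))
  expect_true(all(rep$stages$surviving <= rep$stages$input))
  expect_equal(length(rep$eliminated) + length(rep$accepted), nrow(codes))
  # feature summary is recomputed directly from the sequences
  feats <- rep$features
  expect_equal(feats$gc,
               unname(vapply(feats$transcript_id,
                             function(i) gc_content(seqs[[i]]), numeric(1))),
               tolerance = 1e-12)
  .fixtures$screen_report <- rep
  .fixtures$screen_inputs <- list(codes = codes, seqs = seqs, known = known,
                                  mirna = mirna, fpkm = fpkm)
})

test_that("disabling any single stage yields a superset of the accepted set", {
  si <- .fixtures$screen_inputs
  base <- .fixtures$screen_report$accepted
  run <- function(...) run_screening_pipeline(
    si$codes, si$seqs, si$known, si$mirna, si$fpkm, ...)$accepted
  variants <- list(
    run(keep_codes = c("i", "o", "u", "j", "x", "=", "other")),
    run(min_length = 1),
    run(sim_max_e = 1e-300),          # known/miRNA hits can never pass
    run(orf_min = .Machine$integer.max),
    run(fpkm_floor = 0))
  for (acc in variants) {
    expect_true(all(base %in% acc))
    expect_gte(length(acc), length(base))
  }
})
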