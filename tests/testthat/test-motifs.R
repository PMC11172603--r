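# Motif scanning and architecture classification.

test_motifs <- list(motif_model(1, "TGACCGTTGAGC", 1),
                    motif_model(2, "ACCGTAGGCTAA", 1),
                    motif_model(3, "GGTCAATCGCAT", 1))

spaced <- function(ids, gap = 15) {
  parts <- character(0)
  for (i in seq_along(ids)) {
    parts <- c(parts, strrep("A", gap),
               test_motifs[[ids[i]]]$consensus)
  }
  paste0(paste(parts, collapse = ""), strrep("A", gap))
}

test_that("motif model validation enforces length and mismatch bounds", {
  expect_error(motif_model(1, "ACGT"), "at least 6")
  expect_error(motif_model(1, "ACGTACGTACGT", 4), "length / 3")
})

test_that("exact occurrences are found with full score on either strand", {
  s <- paste0(strrep("C", 9), test_motifs[[1]]$consensus, strrep("C", 9))
  occ <- scan_motifs(s, test_motifs[1])
  expect_equal(occ$start, 10L)
  expect_equal(occ$score, 12L)
  expect_equal(occ$strand, "+")
  rc <- paste0(strrep("C", 9),
               stresslnc:::revcomp_chr(test_motifs[[1]]$consensus),
               strrep("C", 9))
  occ2 <- scan_motifs(rc, test_motifs[1])
  expect_equal(occ2$strand, "-")
  # sequences shorter than the motif yield an empty result
  expect_equal(nrow(scan_motifs("ACGT", test_motifs)), 0)
})

test_that("mismatch allowance and greedy overlap resolution work", {
  cons <- test_motifs[[1]]$consensus
  one_off <- paste0("A", substr(cons, 2, 12))
  s <- paste0(strrep("C", 9), one_off, strrep("C", 9))
  occ <- scan_motifs(s, test_motifs[1])
  expect_equal(occ$score, 11L)  # 12 positions, 1 mismatch
  # the exact copy wins over an overlapping 1-mismatch shifted copy
  s2 <- paste0(strrep("C", 5), cons, strrep("C", 20))
  occ2 <- scan_motifs(s2, test_motifs[1])
  expect_equal(nrow(occ2), 1)
  expect_equal(occ2$score, 12L)
})

test_that("architecture strings and class labels follow the 5'->3' first-occurrence rule", {
  a312 <- classify_architecture(scan_motifs(spaced(c(3, 1, 2)), test_motifs),
                                nchar(spaced(c(3, 1, 2))))
  expect_equal(a312$architecture, "312")
  expect_equal(a312$class_label, "class1")
  a213 <- classify_architecture(scan_motifs(spaced(c(2, 1, 3)), test_motifs),
                                nchar(spaced(c(2, 1, 3))))
  expect_equal(a213$architecture, "213")
  expect_equal(a213$class_label, "class2")
  other <- classify_architecture(scan_motifs(spaced(c(1, 2, 3)), test_motifs),
                                 nchar(spaced(c(1, 2, 3))))
  expect_equal(other$class_label, "other")
})

test_that("a duplicated motif 2 is an expansion and does not change the class", {
  s <- spaced(c(3, 1, 2, 2))
  cl <- classify_architecture(scan_motifs(s, test_motifs), nchar(s))
  expect_equal(cl$architecture, "312")
  expect_equal(cl$class_label, "class1")
  expect_equal(unname(cl$expansions["2"]), 2L)
})

test_that("classification is invariant under reverse complement", {
  for (ids in list(c(3, 1, 2), c(2, 1, 3), c(3, 1, 2, 2))) {
    s <- spaced(ids)
    fwd <- classify_architecture(scan_motifs(s, test_motifs), nchar(s))
    rc <- stresslnc:::revcomp_chr(s)
    rev <- classify_architecture(scan_motifs(rc, test_motifs), nchar(rc))
    expect_equal(rev$class_label, fwd$class_label)
    expect_equal(rev$architecture, fwd$architecture)
  }
})

test_that("random sequences rarely contain a 12-mer motif at 0 mismatches", {
  # expected hit rate per sequence ~ 2 * L / 4^12 (both strands); with
  # L = 300 over 2,000 trials the expected total is ~0.07 hits
  set.seed(23)
  m <- list(motif_model(1, "TGACCGTTGAGC", 0))
  hits <- 0
  for (i in 1:2000) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    hits <- hits + nrow(scan_motifs(s, m))
  }
  expect_lte(hits, 3)
})

test_that("planted family architectures are recovered perfectly", {
  cfg <- sim_config(seed = 31)
  fam <- generate_homolog_families(cfg)
  seqs <- unlist(unname(fam$sequences))
  got <- classify_family_architectures(seqs, cfg$motif_models)
  truth <- fam$truth
  m <- merge(got, truth, by = "sequence_id")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$class_label.x == m$class_label.y))
  # expansions recorded for the motif-2 duplicated members
  expanded <- truth$sequence_id[truth$motif2_expanded]
  expect_true(all(grepl("2", got$expanded_motifs[match(expanded,
                                                       got$sequence_id)])))
})

test_that("motif readers parse consensus TSV and MEME text", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tconsensus\tmax_mismatches",
               "1\tTGACCGTTGAGC\t1"), tsv)
  m <- read_motif_tsv(tsv)
  expect_equal(m[[1]]$consensus, "TGACCGTTGAGC")
  meme <- tempfile(fileext = ".txt")
  writeLines(c("MEME version 5.5.5", "", "MOTIF TGACCGTTGAGC MEME-1",
               "letter-probability matrix: ...", "", "MOTIF ACCGTAGGCTAA MEME-2"),
             meme)
  mm <- read_meme_motifs(meme)
  expect_equal(length(mm), 2)
  expect_equal(mm[[2]]$consensus, "ACCGTAGGCTAA")
})
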