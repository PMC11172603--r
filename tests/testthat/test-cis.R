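# Cis-target prediction, TF tallying and hypergeometric enrichment.

mk_tx <- function(id, gid, chr, start, end, strand = "+") {
  data.frame(transcript_id = id, gene_id = gid, seqnames = chr,
             strand = strand, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("window qualification is inclusive at the boundary and 0 for overlaps", {
  lnc <- mk_tx("L1", "XL1", "chr1", 500000, 501000)
  genes <- rbind(
    mk_tx("P1", "G_overlap", "chr1", 500500, 502000),
    mk_tx("P2", "G_at_window", "chr1", 601001, 602000),   # gap exactly 100000
    mk_tx("P3", "G_past_window", "chr1", 601002, 603000), # gap 100001
    mk_tx("P4", "G_upstream", "chr1", 395000, 399999),    # gap 100000 upstream
    mk_tx("P5", "G_other_chr", "chr2", 500000, 501000))
  nb <- window_neighbors(lnc, genes, window = 100000)
  expect_setequal(nb$pcg_gene, c("G_overlap", "G_at_window", "G_upstream"))
  expect_equal(nb$distance[nb$pcg_gene == "G_overlap"], 0)
  expect_equal(nb$distance[nb$pcg_gene == "G_at_window"], 100000)
  # missing chromosome in the gene annotation is an error
  lnc2 <- mk_tx("L2", "XL2", "chr9", 1000, 2000)
  expect_error(window_neighbors(lnc2, genes), "chr9")
})

test_that("cis rule: PCC sign matters, zero variance is flagged, permutation invariant", {
  cands <- data.frame(lncrna_gene = c("L1", "L1", "L1"),
                      pcg_gene = c("Pid", "Panti", "Pflat"),
                      distance = c(0, 10, 20))
  set.seed(20)
  x <- 2^rnorm(24)
  m <- rbind(L1 = x, Pid = x * 3, Panti = max(x) + 1 - x, Pflat = rep(2, 24))
  colnames(m) <- sprintf("s%02d", 1:24)
  cp <- cis_pairs(cands, m)
  expect_equal(cp$pcc[1], 1, tolerance = 1e-12)
  expect_true(cp$passes[1])
  expect_lt(cp$pcc[2], 0)          # anti-correlated
  expect_false(cp$passes[2])       # one-sided rule rejects it
  expect_true(cp$undefined[3]); expect_false(cp$passes[3])
  # signed option admits strong anti-correlation
  expect_true(cis_pairs(cands, m, signed = TRUE)$passes[2])
  # joint sample permutation leaves results unchanged
  perm <- sample(24)
  cp2 <- cis_pairs(cands, m[, perm])
  expect_equal(cp2$pcc, cp$pcc, tolerance = 1e-12)
  # ids absent from the matrix are an error
  expect_error(cis_pairs(data.frame(lncrna_gene = "L9", pcg_gene = "Pid",
                                    distance = 1), m), "absent")
})

test_that("planted cis pairs pass and agree with a brute-force scan", {
  sd <- small_dataset()
  asm <- read_gtf(file.path(sd$dir, "assembled.gtf"))
  ref <- read_gtf(file.path(sd$dir, "reference.gtf"))
  fpkm <- read_fpkm(file.path(sd$dir, "fpkm.tsv"))
  truth <- read_tsv(file.path(sd$dir, "truth", "truth_cis.tsv"))
  lnc_ids <- truth$lncrna_id
  lnc_tx <- asm[asm$transcript_id %in% lnc_ids, ]
  nb <- window_neighbors(lnc_tx, ref, window = 100000)

  # brute force over all lnc x gene span pairs
  lspan <- do.call(rbind, lapply(split(lnc_tx, lnc_tx$gene_id), function(x)
    data.frame(gene = x$gene_id[1], chr = x$seqnames[1],
               s = min(x$start), e = max(x$end))))
  gspan <- do.call(rbind, lapply(split(ref, ref$gene_id), function(x)
    data.frame(gene = x$gene_id[1], chr = x$seqnames[1],
               s = min(x$start), e = max(x$end))))
  brute <- 0
  for (i in seq_len(nrow(lspan))) for (j in seq_len(nrow(gspan))) {
    if (lspan$chr[i] != gspan$chr[j]) next
    gap <- max(0, max(lspan$s[i], gspan$s[j]) - min(lspan$e[i], gspan$e[j]) - 1)
    if (gap <= 100000) brute <- brute + 1
  }
  expect_equal(nrow(nb), brute)

  # planted partners appear among candidates at the planted distance, and
  # their expression correlation passes the cis rule
  lmap <- setNames(lnc_tx$transcript_id[!duplicated(lnc_tx$gene_id)],
                   lnc_tx$gene_id[!duplicated(lnc_tx$gene_id)])
  pmap <- setNames(ref$transcript_id[!duplicated(ref$gene_id)],
                   ref$gene_id[!duplicated(ref$gene_id)])
  cp <- cis_pairs(nb, fpkm, lnc_map = lmap, pcg_map = pmap)
  key <- paste(cp$lncrna_id, cp$pcg_id)
  tkey <- paste(truth$lncrna_id, truth$pcg_id)
  expect_true(all(tkey %in% key))
  planted <- cp[match(tkey, key), ]
  expect_true(all(planted$passes))
  expect_equal(planted$distance, truth$distance)
  # the far lncRNA (gap 100001) is not among its partner's candidates
  tr <- small_truth()
  far <- tr[tr$role == "lnc_far", ]
  far_tx <- asm[asm$transcript_id == far$transcript_id, ]
  nb_far <- window_neighbors(far_tx, ref, window = 100000)
  expect_false(far$cis_partner[1] %in%
                 paste0(nb_far$pcg_gene, ".1"))
})

test_that("TF tally counts targets by family and conserves totals", {
  tf <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   family = c("MYB", "MYB", "WRKY", "NAC"))
  expect_equal(nrow(tf_family_tally(character(0), tf)), 0)
  tal <- tf_family_tally(c("g1", "g2", "g3", "g9"), tf)
  expect_equal(tal$count[tal$family == "MYB"], 2L)
  expect_equal(sum(tal$count), 3L)  # g9 is absent from the table
  expect_error(tf_family_tally("g1", data.frame(x = 1)), "gene_id")
})

test_that("hypergeometric enrichment: exact p-values, universal term, BH", {
  # N = 10, K = 5, n = 5, k = 5 -> 1 / C(10,5)
  pop <- sprintf("g%02d", 1:10)
  ann <- rbind(data.frame(gene_id = pop[1:5], term_id = "T1"),
               data.frame(gene_id = pop, term_id = "Tall"))
  res <- hypergeometric_enrichment(pop[1:5], pop, ann)
  expect_equal(res$p_value[res$term_id == "T1"], 1 / choose(10, 5),
               tolerance = 1e-12)
  # a term annotating the whole population has p = 1
  expect_equal(res$p_value[res$term_id == "Tall"], 1, tolerance = 1e-12)
  # study must be a subset of the population
  expect_error(hypergeometric_enrichment(c("zz"), pop, ann), "subset")
  # p-values are invariant to gene renaming
  ren <- function(x) paste0("x_", x)
  res2 <- hypergeometric_enrichment(ren(pop[1:5]), ren(pop),
                                    transform(ann, gene_id = ren(gene_id)))
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-15)
})

test_that("OBO depths parse and slice enrichment to a level", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: root", "",
               "[Term]", "id: GO:0000002", "name: child",
               "is_a: GO:0000001 ! root", "",
               "[Term]", "id: GO:0000003", "name: grandchild",
               "is_a: GO:0000002 ! child"), obo)
  d <- read_obo_depths(obo)
  expect_equal(unname(d[c("GO:0000001", "GO:0000002", "GO:0000003")]),
               c(0L, 1L, 2L))
  pop <- sprintf("g%02d", 1:10)
  ann <- rbind(data.frame(gene_id = pop[1:5], term_id = "GO:0000002"),
               data.frame(gene_id = pop[1:5], term_id = "GO:0000003"))
  res <- hypergeometric_enrichment(pop[1:5], pop, ann, term_depths = d,
                                   level = 1)
  expect_equal(res$term_id, "GO:0000002")
})

test_that("the hypergeometric pmf is normalised", {
  set.seed(22)
  for (rep in 1:20) {
    N <- sample(10:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    ks <- max(0, n + K - N):min(K, n)
    expect_equal(sum(dhyper(ks, K, N - K, n)), 1, tolerance = 1e-12)
  }
})
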