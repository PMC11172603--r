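# Class-code assignment: definition cases, priority, invariances, and
# equivalence with the exhaustive oracle.

ref3 <- data.frame(transcript_id = "R1", gene_id = "G1", seqnames = "chr1",
                   strand = "+", start = c(100, 300, 600),
                   end = c(200, 400, 700), stringsAsFactors = FALSE)

mkq <- function(start, end, strand = "+", chr = "chr1", id = "Q") {
  data.frame(transcript_id = id, gene_id = paste0(id, "g"), seqnames = chr,
             strand = strand, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("each class-code definition is recognised", {
  # identical intron chain, differing ends -> "="
  expect_equal(assign_class_code(mkq(c(90, 300, 600), c(200, 400, 720)),
                                 ref3)$code, "=")
  # shares the first intron only -> "j"
  expect_equal(assign_class_code(mkq(c(150, 300), c(200, 380)), ref3)$code, "j")
  # single exon inside intron 1 -> "i"
  expect_equal(assign_class_code(mkq(210, 290), ref3)$code, "i")
  # exonic overlap, opposite strand -> "x"
  expect_equal(assign_class_code(mkq(150, 250, strand = "-"), ref3)$code, "x")
  # same-strand exonic overlap, no shared intron -> "o"
  expect_equal(assign_class_code(mkq(150, 250), ref3)$code, "o")
  # no overlap at all -> "u"
  res <- assign_class_code(mkq(5000, 5500), ref3)
  expect_equal(res$code, "u")
  expect_true(is.na(res$matched_reference_id))
})

test_that("unstranded queries are never antisense and single-exon '=' needs reciprocal overlap", {
  expect_equal(assign_class_code(mkq(150, 250, strand = "."), ref3)$code, "o")
  ref1 <- mkq(100, 400, id = "R1")
  # 90% reciprocal overlap of two single-exon models -> "="
  expect_equal(assign_class_code(mkq(110, 400, id = "Q1"), ref1)$code, "=")
  # 50% overlap fails the 80% rule -> "o"
  expect_equal(assign_class_code(mkq(250, 550, id = "Q2"), ref1)$code, "o")
})

test_that("strand flip of query and references leaves codes unchanged", {
  set.seed(11)
  ref <- random_reference(20)
  q <- random_queries(40, ref)
  flip <- function(s) chartr("+-", "-+", s)
  a <- compare_annotations(q, ref)
  q2 <- q; q2$strand <- flip(q2$strand)
  ref2 <- ref; ref2$strand <- flip(ref2$strand)
  b <- compare_annotations(q2, ref2)
  expect_equal(a$class_code, b$class_code)
})

test_that("batch comparison equals per-query assignment and is order-independent", {
  set.seed(5)
  ref <- random_reference(15)
  q <- random_queries(30, ref)
  batch <- compare_annotations(q, ref)
  for (tid in batch$transcript_id) {
    single <- assign_class_code(q[q$transcript_id == tid, ], ref)
    expect_equal(batch$class_code[batch$transcript_id == tid], single$code)
  }
  # permuted input order gives the same (sorted) table
  perm <- q[sample(nrow(q)), ]
  expect_equal(compare_annotations(perm, ref), batch)
})

test_that("error contracts: empty exon list, duplicate ids, empty query set", {
  expect_error(assign_class_code(ref3[0, ], ref3), "empty exon list")
  dup <- rbind(mkq(100, 200, id = "D1"), mkq(5000, 5100, chr = "chr2", id = "D1"))
  expect_error(compare_annotations(dup, ref3), "duplicate.*D1")
  empty <- compare_annotations(ref3[0, ], ref3)
  expect_equal(nrow(empty), 0)
})

test_that("indexed classifier agrees with the exhaustive oracle on random instances", {
  set.seed(99)
  ref <- random_reference(60)
  q <- random_queries(250, ref)
  got <- compare_annotations(q, ref)
  for (tid in got$transcript_id) {
    qq <- q[q$transcript_id == tid, ]
    qq <- qq[order(qq$start), ]
    want <- oracle_class_code(as.matrix(qq[c("start", "end")]),
                              qq$strand[1], qq$seqnames[1], ref)
    expect_equal(got$class_code[got$transcript_id == tid], want,
                 label = sprintf("query %s", tid))
  }
})
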