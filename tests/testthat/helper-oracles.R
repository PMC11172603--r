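# Independent oracles and shared fixtures for the test suite.  The oracles
# deliberately avoid the package's own code paths: the class-code oracle is
# a plain exhaustive loop over interval arithmetic, the alignment oracle is
# a full (unbanded) Gotoh dynamic program, and the hypergeometric oracle is
# a direct sum of binomial-coefficient ratios.

# ---- brute-force class-code oracle -----------------------------------------

oracle_introns <- function(ex) {
  if (nrow(ex) < 2) return(matrix(numeric(0), ncol = 2))
  cbind(ex[-nrow(ex), 2] + 1, ex[-1, 1] - 1)
}

oracle_overlap_len <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ov <- min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]) + 1
    if (ov > 0) tot <- tot + ov
  }
  tot
}

# classify one query against all reference transcripts by exhaustive
# enumeration of the code definitions, then apply the priority order
oracle_class_code <- function(qex, qstrand, qchr, ref, single_exon_frac = 0.8) {
  prio <- c("=" = 1, "j" = 2, "o" = 3, "x" = 4, "i" = 5, "u" = 6)
  best <- "u"
  for (rid in unique(ref$transcript_id)) {
    rr <- ref[ref$transcript_id == rid, ]
    if (rr$seqnames[1] != qchr) next
    rex <- as.matrix(rr[order(rr$start), c("start", "end")])
    rstrand <- rr$strand[1]
    same <- qstrand == "." || rstrand == "." || qstrand == rstrand
    oppo <- (qstrand == "+" && rstrand == "-") ||
            (qstrand == "-" && rstrand == "+")
    ov <- oracle_overlap_len(qex, rex)
    qin <- oracle_introns(qex); rin <- oracle_introns(rex)
    codes <- character(0)
    if (same && nrow(qex) > 1 && nrow(rex) > 1 &&
        nrow(qin) == nrow(rin) && all(qin == rin)) codes <- c(codes, "=")
    if (same && nrow(qex) == 1 && nrow(rex) == 1 && ov > 0) {
      qlen <- qex[1, 2] - qex[1, 1] + 1; rlen <- rex[1, 2] - rex[1, 1] + 1
      if (ov / qlen >= single_exon_frac && ov / rlen >= single_exon_frac)
        codes <- c(codes, "=")
    }
    if (same && nrow(qin) > 0 && nrow(rin) > 0) {
      shared <- FALSE
      for (i in seq_len(nrow(qin))) for (j in seq_len(nrow(rin)))
        if (all(qin[i, ] == rin[j, ])) shared <- TRUE
      if (shared) codes <- c(codes, "j")
    }
    if (same && ov > 0) codes <- c(codes, "o")
    if (oppo && ov > 0) codes <- c(codes, "x")
    if (same && nrow(rin) > 0) {
      qlo <- min(qex[, 1]); qhi <- max(qex[, 2])
      for (j in seq_len(nrow(rin)))
        if (rin[j, 1] <= qlo && rin[j, 2] >= qhi) codes <- c(codes, "i")
    }
    for (cd in codes) if (prio[cd] < prio[best]) best <- cd
  }
  best
}

# random transcript instance generators for the classifier oracle test
random_reference <- function(n_genes, chrlen = 200000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genes)) {
    chr <- sample(c("chr1", "chr2"), 1)
    start <- sample(seq(1, chrlen - 5000), 1)
    ne <- sample(1:4, 1)
    elen <- sample(80:400, ne, replace = TRUE)
    ilen <- if (ne > 1) sample(60:500, ne - 1, replace = TRUE) else integer(0)
    es <- start + c(0, cumsum(elen[-ne] + ilen))
    rows[[g]] <- data.frame(
      transcript_id = sprintf("R%03d", g), gene_id = sprintf("RG%03d", g),
      seqnames = chr, strand = sample(c("+", "-"), 1),
      start = es, end = es + elen - 1, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

random_queries <- function(n, ref, chrlen = 200000) {
  rows <- list()
  for (q in seq_len(n)) {
    if (runif(1) < 0.7 && nrow(ref)) {
      # anchor near a random reference transcript so non-u codes occur
      anchor <- ref[ref$transcript_id == sample(unique(ref$transcript_id), 1), ]
      chr <- anchor$seqnames[1]
      base <- max(1, min(anchor$start) + sample(-600:600, 1))
    } else {
      chr <- sample(c("chr1", "chr2"), 1)
      base <- sample(seq(1, chrlen - 3000), 1)
    }
    ne <- sample(1:3, 1)
    elen <- sample(60:500, ne, replace = TRUE)
    ilen <- if (ne > 1) sample(50:400, ne - 1, replace = TRUE) else integer(0)
    es <- base + c(0, cumsum(elen[-ne] + ilen))
    rows[[q]] <- data.frame(
      transcript_id = sprintf("Q%04d", q), gene_id = sprintf("QG%04d", q),
      seqnames = chr, strand = sample(c("+", "-", "."), 1, prob = c(.45, .45, .1)),
      start = es, end = es + elen - 1, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# ---- full (unbanded) Smith-Waterman oracle ----------------------------------

oracle_sw <- function(query, subject, match = 1, mismatch = -2,
                      gap_open = 5, gap_extend = 2) {
  q <- strsplit(toupper(query), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  m <- length(q); n <- length(s)
  NEG <- -1e9
  gopen <- gap_open + gap_extend
  H <- matrix(0, m + 1, n + 1); E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1); P <- matrix(0L, m + 1, n + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:m) for (j in 1:n) {
    sub <- if (q[i] == s[j]) match else mismatch
    e <- max(H[i + 1, j] - gopen, E[i + 1, j] - gap_extend)
    f <- max(H[i, j + 1] - gopen, F[i, j + 1] - gap_extend)
    hd <- H[i, j] + sub
    h <- max(0, hd, e, f)
    H[i + 1, j + 1] <- h; E[i + 1, j + 1] <- e; F[i + 1, j + 1] <- f
    P[i + 1, j + 1] <- if (h == 0) 0L else if (h == hd) 1L else if (h == f) 2L else 3L
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  if (best <= 0) return(list(score = 0, identity = 0))
  i <- bi; j <- bj; matches <- 0; alen <- 0
  while (i >= 1 && j >= 1) {
    p <- P[i + 1, j + 1]
    if (p == 0L) break
    alen <- alen + 1
    if (p == 1L) { if (q[i] == s[j]) matches <- matches + 1; i <- i - 1; j <- j - 1 }
    else if (p == 2L) i <- i - 1
    else j <- j - 1
  }
  list(score = best, identity = 100 * matches / alen)
}

# ---- hypergeometric upper-tail oracle ---------------------------------------

oracle_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# ---- shared synthetic dataset fixtures --------------------------------------

.fixtures <- new.env(parent = emptyenv())

# small planted dataset: 50 planted lncRNAs + 90 negatives on a compact
# genome; shared across screening / expression / pipeline tests
small_dataset <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  dir <- file.path(tempdir(), "stresslnc_small")
  cfg <- sim_config(seed = 424, n_pcg = 150L, chrom_length = 1.4e6)
  res <- simulate_dataset(cfg, dir)
  .fixtures$small <- list(dir = dir, cfg = cfg, res = res)
  .fixtures$small
}

small_truth <- function() {
  sd <- small_dataset()
  read_tsv(file.path(sd$dir, "truth", "truth_transcripts.tsv"))
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# md5 of every file under a directory (relative names), excluding run.log
dir_md5 <- function(dir, exclude = "run.log") {
  files <- list.files(dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, exclude)
  md5 <- tools::md5sum(file.path(dir, files))
  stats::setNames(unname(md5), files)
}

# adjusted Rand index between two labelings (direct pair-counting formula)
rand_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- ai * bj / np
  (sij - expected) / ((ai + bj) / 2 - expected)
}
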