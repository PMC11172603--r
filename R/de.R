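# Differential expression under stress, genotype-relatedness classification,
# response partitioning, stress-activated selection, and the nonparametric
# group tests used in the results.  The DE test is a declared stand-in for
# the count-model tool used upstream of FPKM matrices: a two-sample
# pooled-variance t on log2(FPKM + 1), with log2 fold change computed on
# pseudo-counted means (c = 0.25 FPKM, below the presence floor of 0.5 so it
# can never create presence) and Benjamini-Hochberg adjustment within the
# contrast.  The significance thresholds are |log2FC| >= 0.5, p <= 0.05,
# q <= 0.05.  The variance is pooled (not Welch-corrected) deliberately:
# with two replicates per cell the Satterthwaite degrees of freedom collapse
# toward one, giving the test a 1/t p-value tail and essentially no power
# after FDR adjustment, while the design guarantees equal group sizes and a
# shared noise model, the textbook condition for pooling.

.design_cells <- function(design, genotype, tissue, treatment) {
  design$sample_id[design$genotype == genotype & design$tissue == tissue &
                   design$treatment == treatment]
}

# vectorised pooled-variance two-sample t on rows of two matrices
.t_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se2 <- sp2 * (1 / n1 + 1 / n2)
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = df)
  # degenerate rows: zero variance in both groups
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

#' Differential expression for one treatment-vs-control contrast
#'
#' @param matrix FPKM matrix (transcripts x samples).
#' @param design design table (see [read_design()]).
#' @param genotype,tissue the design cell pair shares these.
#' @param treatment treated level (compared with `control`).
#' @param lfc_min,p_max,q_max significance thresholds (defaults 0.5 / 0.05 /
#'   0.05).
#' @param pseudo pseudo-count for the fold change (default 0.25 FPKM).
#' @return data.frame of per-transcript records: `transcript_id`, `contrast`,
#'   `log2fc`, `p_value`, `q_value`, `significant`, `direction`.
#' @export
differential_expression <- function(matrix, design, genotype, tissue,
                                    treatment, lfc_min = 0.5, p_max = 0.05,
                                    q_max = 0.05, pseudo = 0.25) {
  trt <- .design_cells(design, genotype, tissue, treatment)
  ctl <- .design_cells(design, genotype, tissue, "control")
  if (length(trt) < 2 || length(ctl) < 2)
    stopf("contrast %s:%s:%s-vs-control needs >= 2 replicates per cell",
          genotype, tissue, treatment)
  a <- matrix[, trt, drop = FALSE]
  b <- matrix[, ctl, drop = FALSE]
  lfc <- log2((rowMeans(a) + pseudo) / (rowMeans(b) + pseudo))
  p <- .t_rows(log2(a + 1), log2(b + 1))
  q <- stats::p.adjust(p, method = "BH")
  sig <- abs(lfc) >= lfc_min & p <= p_max & q <= q_max
  data.frame(
    transcript_id = rownames(matrix),
    contrast = sprintf("%s:%s:%s-vs-control", genotype, tissue, treatment),
    log2fc = lfc, p_value = p, q_value = q, significant = sig,
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify transcripts by genotype relatedness
#'
#' A transcript is *present* in a genotype when its maximum FPKM over that
#' genotype's samples reaches `presence_threshold`.  Transcripts present in
#' both genotypes are `non-related`; transcripts whose presence differs are
#' `related` (their presence depends on the wild-type allele); transcripts
#' absent from both are `undetected`.
#'
#' @param matrix FPKM matrix.
#' @param design design table.
#' @param presence_threshold FPKM presence floor (default 0.5).
#' @param per_tissue when TRUE, presence is computed within each tissue and
#'   one label is returned per transcript x tissue.
#' @return data.frame with `transcript_id`, (`tissue`,) `presence_wt`,
#'   `presence_mut`, `label`.
#' @export
classify_relatedness <- function(matrix, design, presence_threshold = 0.5,
                                 per_tissue = FALSE) {
  lab_one <- function(cols_wt, cols_mut, tissue = NA_character_) {
    pw <- apply(matrix[, cols_wt, drop = FALSE], 1, max) >= presence_threshold
    pm <- apply(matrix[, cols_mut, drop = FALSE], 1, max) >= presence_threshold
    label <- ifelse(pw & pm, "non-related",
             ifelse(!pw & !pm, "undetected", "related"))
    df <- data.frame(transcript_id = rownames(matrix),
                     presence_wt = pw, presence_mut = pm, label = label,
                     stringsAsFactors = FALSE, row.names = NULL)
    if (!is.na(tissue)) df <- cbind(df[1], tissue = tissue, df[-1])
    df
  }
  wt <- design$sample_id[design$genotype == "WT"]
  mut <- design$sample_id[design$genotype != "WT"]
  if (!length(wt) || !length(mut))
    stopf("classify_relatedness: both genotypes must be present in the design")
  if (!per_tissue) return(lab_one(wt, mut))
  out <- lapply(unique(design$tissue), function(ts) {
    lab_one(intersect(wt, design$sample_id[design$tissue == ts]),
            intersect(mut, design$sample_id[design$tissue == ts]), ts)
  })
  do.call(rbind, out)
}

#' Partition transcripts by stress-response specificity
#'
#' @param de_salt,de_sorbitol DE record tables from
#'   [differential_expression()] for the NaCl and sorbitol contrasts of the
#'   same tissue, on the same transcript universe.
#' @param tissue label recorded in the output.
#' @return data.frame with `transcript_id`, `tissue`, `category` in
#'   `salt-specific`, `hyperosmolarity-specific`, `co-responsive`,
#'   `non-responsive`.
#' @export
partition_response <- function(de_salt, de_sorbitol, tissue) {
  if (!identical(sort(de_salt$transcript_id), sort(de_sorbitol$transcript_id)))
    stopf("partition_response: DE sets are on different transcript universes")
  ids <- de_salt$transcript_id
  sig_salt <- de_salt$significant
  sig_sorb <- de_sorbitol$significant[match(ids, de_sorbitol$transcript_id)]
  category <- ifelse(sig_salt & sig_sorb, "co-responsive",
              ifelse(sig_salt, "salt-specific",
              ifelse(sig_sorb, "hyperosmolarity-specific", "non-responsive")))
  data.frame(transcript_id = ids, tissue = tissue, category = category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stress-activated transcripts (up-regulated in both tissues)
#'
#' A transcript is stress-activated in seedlings when it is significantly
#' up-regulated in *both* the shoot and the root contrast of the same
#' genotype and treatment.
#'
#' @param de_shoot,de_root DE record tables for the two tissues.
#' @return character vector of transcript ids.
#' @export
find_stress_activated <- function(de_shoot, de_root) {
  up_shoot <- de_shoot$transcript_id[de_shoot$significant &
                                     de_shoot$direction == "up"]
  up_root <- de_root$transcript_id[de_root$significant &
                                   de_root$direction == "up"]
  sort(intersect(up_shoot, up_root))
}

#' Relatedness x stress-response combination
#'
#' Combines genotype-relatedness labels with DE calls to select related
#' stress-responsive transcripts.  Because the Boolean combination across
#' genotypes is a modelling choice, both variants are returned as flag
#' columns: `responsive_wt` (DE in the WT contrast) and `responsive_either`
#' (DE in either genotype's contrast).
#'
#' @param relatedness output of [classify_relatedness()].
#' @param de_wt,de_mut DE tables for the same tissue/treatment contrast in
#'   the two genotypes.
#' @return data.frame with `transcript_id`, `related`, `responsive_wt`,
#'   `responsive_either`.
#' @export
related_stress_responsive <- function(relatedness, de_wt, de_mut) {
  ids <- relatedness$transcript_id
  rel <- relatedness$label == "related"
  sw <- de_wt$significant[match(ids, de_wt$transcript_id)]
  sm <- de_mut$significant[match(ids, de_mut$transcript_id)]
  sw[is.na(sw)] <- FALSE; sm[is.na(sm)] <- FALSE
  data.frame(transcript_id = ids, related = rel,
             responsive_wt = rel & sw,
             responsive_either = rel & (sw | sm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-group comparison tests
#'
#' Thin dispatcher over the exact tests used for group comparisons:
#' two-sided Mann-Whitney U, two-sided Wilcoxon signed-rank on paired
#' vectors, and two-sided Fisher's exact test on a 2x2 table.
#'
#' @param a first sample (or the 2x2 integer matrix for `fisher-exact`).
#' @param b second sample (ignored for `fisher-exact`).
#' @param test one of `"mann-whitney"`, `"wilcoxon-signed-rank"`,
#'   `"fisher-exact"`.
#' @return list with `statistic` and `p_value` (two-sided).
#' @export
group_comparison <- function(a, b = NULL,
                             test = c("mann-whitney", "wilcoxon-signed-rank",
                                      "fisher-exact")) {
  test <- match.arg(test)
  if (test == "mann-whitney") {
    res <- stats::wilcox.test(a, b, paired = FALSE, alternative = "two.sided",
                              exact = NULL)
    return(list(statistic = unname(res$statistic), p_value = res$p.value))
  }
  if (test == "wilcoxon-signed-rank") {
    if (length(a) != length(b))
      stopf("wilcoxon-signed-rank needs paired vectors of equal length")
    if (all(a == b))
      stopf("wilcoxon-signed-rank undefined: no non-zero differences")
    res <- stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided",
                              exact = NULL)
    return(list(statistic = unname(res$statistic), p_value = res$p.value))
  }
  tab <- a
  if (!is.matrix(tab) || any(dim(tab) != c(2, 2)))
    stopf("fisher-exact needs a 2x2 table")
  if (any(tab < 0)) stopf("fisher-exact: negative counts")
  res <- stats::fisher.test(tab, alternative = "two.sided")
  list(statistic = unname(res$estimate), p_value = res$p.value)
}
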