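# Differential expression, relatedness, partitions, stress-activated
# selection and the group-comparison tests.

mk_design <- function(n_rep = 2) {
  d <- expand.grid(replicate = seq_len(n_rep),
                   treatment = c("control", "NaCl", "sorbitol"),
                   tissue = c("shoot", "root"),
                   genotype = c("WT", "ososca1.1"), stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_%s_rep%d", d$genotype, d$tissue, d$treatment,
                         d$replicate)
  d
}

test_that("identical values give zero fold change and no significance", {
  design <- mk_design()
  m <- matrix(5, 3, nrow(design),
              dimnames = list(c("a", "b", "c"), design$sample_id))
  de <- differential_expression(m, design, "WT", "root", "sorbitol")
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p_value, rep(1, 3))
  expect_false(any(de$significant))
})

test_that("BH adjustment reproduces the analytic example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
})

test_that("a planted 4-fold change at CV 5% is called significant and up", {
  sim <- simulate_de_matrix(500, n_planted = 60, log2fc = 2, noise_cv = 0.05,
                            seed = 10)
  de <- differential_expression(sim$fpkm, sim$design, "WT", "root", "sorbitol")
  planted_up <- sim$planted[sim$direction == "up"]
  rec <- de[match(planted_up, de$transcript_id), ]
  expect_gte(mean(rec$significant), 0.95)
  expect_true(all(rec$direction[rec$significant] == "up"))
})

test_that("q-values dominate p-values and are monotone in p-rank", {
  sim <- simulate_de_matrix(300, n_planted = 30, seed = 2)
  de <- differential_expression(sim$fpkm, sim$design, "WT", "root", "sorbitol")
  expect_true(all(de$q_value >= de$p_value - 1e-15))
  o <- order(de$p_value)
  expect_true(all(diff(de$q_value[o]) >= -1e-12))
})

test_that("relatedness labels follow the presence set-logic", {
  design <- mk_design()
  m <- rbind(everywhere = rep(1, 24),
             wt_only = c(rep(2, 12), rep(0.4, 12)),
             nowhere = rep(0.2, 24))
  colnames(m) <- design$sample_id
  rel <- classify_relatedness(m, design)
  expect_equal(rel$label, c("non-related", "related", "undetected"))
  expect_true(rel$presence_wt[2]); expect_false(rel$presence_mut[2])
})

test_that("partition categories form a partition and respect the definitions", {
  design <- mk_design()
  set.seed(4)
  m <- matrix(2^rnorm(50 * 24), 50, 24,
              dimnames = list(sprintf("t%02d", 1:50), design$sample_id))
  salt <- differential_expression(m, design, "WT", "root", "NaCl")
  sorb <- differential_expression(m, design, "WT", "root", "sorbitol")
  # force known significance patterns
  salt$significant <- rep(c(TRUE, FALSE), 25)
  sorb$significant <- rep(c(TRUE, TRUE, FALSE, FALSE), length.out = 50)
  part <- partition_response(salt, sorb, "root")
  expect_equal(sort(unique(part$category)),
               sort(c("co-responsive", "salt-specific",
                      "hyperosmolarity-specific", "non-responsive")))
  tab <- table(part$category)
  expect_equal(sum(tab), 50)
  expect_equal(unname(tab["co-responsive"] + tab["salt-specific"]),
               sum(salt$significant))
  # universe mismatch is an error
  expect_error(partition_response(salt[-1, ], sorb, "root"), "universe")
})

test_that("stress-activated selection requires up-regulation in both tissues", {
  de1 <- data.frame(transcript_id = c("a", "b", "c"),
                    significant = c(TRUE, TRUE, FALSE),
                    direction = c("up", "down", "up"))
  de2 <- data.frame(transcript_id = c("a", "b", "c"),
                    significant = c(TRUE, TRUE, TRUE),
                    direction = c("up", "up", "up"))
  expect_equal(find_stress_activated(de1, de2), "a")
})

test_that("group comparisons: Fisher example, Mann-Whitney calibration, degenerate Wilcoxon", {
  gf <- group_comparison(matrix(c(3, 1, 1, 3), 2), test = "fisher-exact")
  expect_equal(gf$p_value, 0.4857143, tolerance = 1e-6)
  expect_error(group_comparison(matrix(c(-1, 1, 1, 3), 2), test = "fisher-exact"),
               "negative")
  expect_error(group_comparison(1:5, 1:5, test = "wilcoxon-signed-rank"),
               "differences")
  # paired Wilcoxon runs on non-degenerate data
  set.seed(6)
  gw <- group_comparison(rnorm(20), rnorm(20, 1), test = "wilcoxon-signed-rank")
  expect_lt(gw$p_value, 0.05)
  # type-I calibration of the Mann-Whitney U at n = 12 vs 12
  set.seed(7)
  rej <- mean(replicate(1000, {
    group_comparison(rnorm(12), rnorm(12), test = "mann-whitney")$p_value <= 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("related stress-responsive combination exposes both genotype variants", {
  rel <- data.frame(transcript_id = c("a", "b", "c"),
                    label = c("related", "related", "non-related"))
  de_wt <- data.frame(transcript_id = c("a", "b", "c"),
                      significant = c(TRUE, FALSE, TRUE))
  de_mut <- data.frame(transcript_id = c("a", "b", "c"),
                       significant = c(FALSE, TRUE, TRUE))
  out <- related_stress_responsive(rel, de_wt, de_mut)
  expect_equal(out$responsive_wt, c(TRUE, FALSE, FALSE))
  expect_equal(out$responsive_either, c(TRUE, TRUE, FALSE))
})
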