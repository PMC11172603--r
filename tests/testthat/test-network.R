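# Co-expression network stage: MAD filter, soft-power selection, TOM,
# module detection, module-trait correlation, hubs and edge export.

test_that("mad_filter applies the low-expression pre-filter then ranks by MAD", {
  set.seed(12)
  m <- rbind(constant = rep(5, 24),
             low = c(rep(0.2, 23), 1.5),
             hi_var = 5 * 2^rnorm(24),
             mid_var = 5 * 2^rnorm(24, sd = 0.3))
  colnames(m) <- sprintf("s%02d", 1:24)
  # low row has FPKM < 1 in 23/24 samples -> removed by the pre-filter
  kept <- mad_filter(m, n_keep = 10)
  expect_false("low" %in% rownames(kept))
  expect_equal(nrow(kept), 3)
  # constant rows (MAD 0) rank last
  expect_false("constant" %in% rownames(mad_filter(m, n_keep = 2)))
  # n_keep = all survivors is the identity on the pre-filtered set
  expect_setequal(rownames(mad_filter(m, n_keep = 3)),
                  c("constant", "hi_var", "mid_var"))
  expect_error(mad_filter(m, n_keep = 0), "positive")
})

test_that("soft-power selection: cutoff 0 gives power 1 and the fit table is complete", {
  set.seed(13)
  m <- matrix(2^rnorm(30 * 12), 30, 12)
  rownames(m) <- sprintf("g%02d", 1:30)
  sp <- pick_soft_power(m, powers = 1:10, r2_cutoff = 0)
  expect_equal(sp$power, 1L)
  expect_false(sp$below_cutoff)
  expect_equal(nrow(sp$fit_table), 10)
  expect_error(pick_soft_power(m[, 1:4]), "8 samples")
})

test_that("a scale-free degree sequence fits with high R^2", {
  # connectivity proportional to 1/rank is the ideal scale-free profile
  k <- 1000 / seq_len(400)
  expect_gt(stresslnc:::scale_free_fit(k), 0.9)
})

test_that("TOM matches the formula on hand-evaluated and random cases", {
  # all-zero adjacency: off-diagonal TOM is 0
  a0 <- matrix(0, 4, 4)
  t0 <- tom_similarity(a0)
  expect_equal(t0[upper.tri(t0)], rep(0, 6))
  expect_equal(diag(t0), rep(1, 4))
  # 3-node adjacency, 0.5 everywhere off-diagonal, by hand:
  # L_ij = 0.25, k_i = 1, TOM_ij = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tt <- tom_similarity(a)
  expect_equal(tt[upper.tri(tt)], rep(0.5, 3), tolerance = 1e-15)
  # direct double-loop formula evaluation on random valid adjacencies
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2; diag(a) <- 0
    tt <- tom_similarity(a)
    expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      L <- sum(a[i, ] * a[, j])
      want <- (L + a[i, j]) / (min(sum(a[i, ]), sum(a[j, ])) + 1 - a[i, j])
      expect_equal(tt[i, j], want, tolerance = 1e-12)
    }
  }
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("planted modules are recovered and label permutation is consistent", {
  cfg <- sim_config(seed = 5, n_modules = 3L, module_size = 40L,
                    noise_cv = 0.3)
  sim <- simulate_module_matrix(cfg)
  lm <- log2(sim$fpkm + 1)
  adj <- adjacency_matrix(lm, 6)
  mods <- detect_modules(1 - tom_similarity(adj), lm, min_module_size = 20)
  expect_equal(length(unique(mods$labels[mods$labels > 0])), 3)
  expect_gte(rand_ari(mods$labels, sim$labels), 0.9)
  # permuting gene order permutes labels consistently
  set.seed(15)
  perm <- sample(nrow(lm))
  adj_p <- adjacency_matrix(lm[perm, ], 6)
  mods_p <- detect_modules(1 - tom_similarity(adj_p), lm[perm, ],
                           min_module_size = 20)
  expect_equal(rand_ari(mods$labels[perm], mods_p$labels), 1)
})

test_that("modules driven by an identical latent merge; perfect modules have |kME| = 1", {
  design_n <- 24
  set.seed(16)
  latent <- rnorm(design_n)
  base <- matrix(rep(latent, each = 60), 60)
  expr <- rbind(base + rnorm(60 * design_n, sd = 0.05),
                base + rnorm(60 * design_n, sd = 0.05))
  rownames(expr) <- sprintf("g%03d", 1:120)
  adj <- adjacency_matrix(expr, 6)
  mods <- detect_modules(1 - tom_similarity(adj), expr, min_module_size = 30)
  # the two planted blocks share the latent -> one merged module
  expect_equal(length(unique(mods$labels[mods$labels > 0])), 1)
  # perfectly correlated module members: |kME| = 1
  perfect <- matrix(rep(latent, each = 40), 40) * rep(runif(40, 0.5, 2), design_n)
  rownames(perfect) <- sprintf("p%02d", 1:40)
  adj2 <- adjacency_matrix(perfect, 6)
  mods2 <- detect_modules(1 - tom_similarity(adj2), perfect,
                          min_module_size = 10)
  own <- mods2$kme[cbind(seq_len(40), 1)]
  expect_equal(abs(own), rep(1, 40), tolerance = 1e-8)
})

test_that("module-trait correlation: exact cases and null uniformity", {
  set.seed(17)
  trait <- rep(c(1, 0), each = 12)
  me <- rbind(ME1 = as.numeric(scale(trait)))
  traits <- rbind(t1 = trait)
  colnames(me) <- colnames(traits) <- sprintf("s%02d", 1:24)
  mt <- module_trait_correlation(me, traits)
  expect_equal(unname(mt$cor[1, 1]), 1, tolerance = 1e-12)
  # r = 0 with n = 24 gives p = 1
  x <- as.numeric(scale(rnorm(24)))
  y <- as.numeric(scale(residuals(lm(rnorm(24) ~ x))))
  me0 <- rbind(ME1 = y); tr0 <- rbind(t1 = x)
  mt0 <- module_trait_correlation(me0, tr0)
  expect_equal(unname(mt0$p[1, 1]), 1, tolerance = 1e-6)
  # zero-variance trait flagged as NA with a warning
  expect_warning(mtz <- module_trait_correlation(me, rbind(z = rep(1, 24))),
                 "zero-variance")
  expect_true(is.na(mtz$cor[1, 1]))
  # null p-values are uniform (Kolmogorov-Smirnov at 1,000 replicates)
  ps <- replicate(1000, {
    a <- rnorm(24); b <- rnorm(24)
    module_trait_correlation(rbind(ME1 = a), rbind(t1 = b))$p[1, 1]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("hub calling is the conjunction of kME and GS cutoffs", {
  labels <- setNames(c(1L, 1L, 1L), c("g1", "g2", "g3"))
  kme <- matrix(c(0.9, 0.6, 0.3), 3, 1, dimnames = list(names(labels), "ME1"))
  set.seed(18)
  trait <- rep(c(1, 0), each = 6)
  expr <- rbind(g1 = trait * 2 + rnorm(12, sd = 1e-3),
                g2 = rnorm(12),          # low GS
                g3 = trait + rnorm(12, sd = 1e-3))
  traits <- rbind(t1 = trait)
  colnames(expr) <- colnames(traits) <- sprintf("s%02d", 1:12)
  me <- rbind(ME1 = as.numeric(scale(trait)))
  colnames(me) <- colnames(traits)
  hubs <- find_hubs(labels, kme, expr, traits, me, cutoff = 0.5)
  expect_equal(hubs$hub, c(TRUE, FALSE, FALSE))  # g2 fails GS, g3 fails kME
  # cutoff 0 makes every member a hub
  hubs0 <- find_hubs(labels, kme, expr, traits, me, cutoff = 0)
  expect_true(all(hubs0$hub))
})

test_that("blockwise detection equals the single-block path below the limit and recovers blocks above it", {
  cfg <- sim_config(seed = 8, n_modules = 3L, module_size = 30L,
                    noise_cv = 0.2)
  sim <- simulate_module_matrix(cfg)
  lm <- log2(sim$fpkm + 1)
  single <- detect_modules(1 - tom_similarity(adjacency_matrix(lm, 6)), lm,
                           min_module_size = 15)
  bw <- blockwise_modules(lm, 6, min_module_size = 15)
  expect_equal(bw$labels, single$labels)
  expect_false(is.null(bw$tom))
  # forcing a split still recovers the planted modules
  set.seed(41)
  bw2 <- blockwise_modules(lm, 6, max_block_size = 45, min_module_size = 15)
  expect_gte(rand_ari(bw2$labels, sim$labels), 0.9)
})

test_that("edge export matches a brute-force count and respects thresholds", {
  set.seed(19)
  n <- 12
  w <- matrix(runif(n * n), n); w <- (w + t(w)) / 2; diag(w) <- 1
  ids <- sprintf("g%02d", 1:n)
  dimnames(w) <- list(ids, ids)
  labels <- setNames(rep(1L, n), ids)
  for (thr in c(0, 0.4, 0.9, 1)) {
    edges <- export_edges(w, labels, 1, thr)
    brute <- sum(w[upper.tri(w)] >= thr)
    expect_equal(nrow(edges), brute)
  }
  expect_equal(nrow(export_edges(w, labels, 1, 0)), n * (n - 1) / 2)
  expect_error(export_edges(w, labels, 99, 0.5), "unknown module")
})
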