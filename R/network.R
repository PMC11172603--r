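# Weighted co-expression network analysis: MAD-based variance filtering,
# soft-threshold selection against a scale-free fit, topological overlap,
# module detection by average-linkage clustering with a static cut plus
# eigengene merging, module-trait correlation, hub calling and thresholded
# edge export.  Adjacency is unsigned, a_ij = |cor(x_i, x_j)|^beta.  The
# dynamic-hybrid tree cut of the reference implementation is replaced by a
# documented static cut at the 0.99 quantile of merge heights; acceptance is
# planted-module recovery, not label-for-label agreement with that
# implementation.

#' MAD filter with a low-expression pre-filter
#'
#' Removes features with FPKM below `min_fpkm` in more than `max_low_frac` of
#' samples, then keeps the `n_keep` features with the highest median absolute
#' deviation (ties broken by transcript id, lexicographic).
#'
#' @param matrix FPKM matrix (transcripts x samples).
#' @param n_keep number of features to keep (default 10000; capped at the
#'   number of pre-filter survivors).
#' @param min_fpkm,max_low_frac pre-filter parameters (defaults 1 FPKM, 0.9).
#' @return reduced matrix.
#' @export
mad_filter <- function(matrix, n_keep = 10000, min_fpkm = 1,
                       max_low_frac = 0.9) {
  if (n_keep <= 0) stopf("mad_filter: n_keep must be positive")
  low_frac <- rowMeans(matrix < min_fpkm)
  m <- matrix[low_frac <= max_low_frac, , drop = FALSE]
  mads <- apply(m, 1, stats::mad)
  ord <- order(-mads, rownames(m))
  keep <- ord[seq_len(min(n_keep, nrow(m)))]
  m[sort(keep), , drop = FALSE]
}

# scale-free topology fit: equal-width binning of the connectivity
# distribution, then regress log10 p(k) on log10 mean k per bin
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2 || diff(range(k)) == 0) return(0)
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tabulate(as.integer(bin), nbins = nlevels(bin)) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  suppressWarnings(summary(fit)$r.squared)
}

#' Select the soft-thresholding power
#'
#' For each candidate power, computes the unsigned adjacency, the
#' connectivity k, and the scale-free fit R^2 of the log-binned degree
#' distribution; returns the smallest power with R^2 at or above the cutoff,
#' or, when none qualifies, the power maximising R^2 with a below-cutoff
#' flag.
#'
#' @param matrix expression matrix (features x samples).
#' @param powers candidate powers (default 1:20).
#' @param r2_cutoff scale-free R^2 cutoff (default 0.85).
#' @return list with `power`, `r2`, `below_cutoff`, and the per-power
#'   `fit_table` (power, r2, mean_k).
#' @export
pick_soft_power <- function(matrix, powers = 1:20, r2_cutoff = 0.85) {
  if (ncol(matrix) < 8)
    stopf("pick_soft_power: at least 8 samples are required")
  ac <- abs(stats::cor(t(matrix)))
  diag(ac) <- 0
  fit <- data.frame(power = powers, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    adj <- ac^powers[i]
    k <- rowSums(adj)
    fit$r2[i] <- scale_free_fit(k)
    fit$mean_k[i] <- mean(k)
  }
  qualifies <- which(fit$r2 >= r2_cutoff)
  if (length(qualifies)) {
    sel <- qualifies[1]
    below <- FALSE
  } else {
    sel <- which.max(fit$r2)
    below <- TRUE
  }
  list(power = powers[sel], r2 = fit$r2[sel], below_cutoff = below,
       fit_table = fit)
}

#' Unsigned adjacency matrix
#' @param matrix expression matrix (features x samples).
#' @param power soft-thresholding power.
#' @return symmetric adjacency with zero diagonal, entries in \[0, 1\].
#' @export
adjacency_matrix <- function(matrix, power) {
  a <- abs(stats::cor(t(matrix)))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum_u a_iu a_uj and k_i = sum_u a_iu; TOM_ii = 1 by convention.
#'
#' @param adjacency symmetric matrix, entries in \[0, 1\], zero diagonal.
#' @return TOM matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-12))
    stopf("tom_similarity: adjacency must be symmetric")
  if (any(adjacency < 0) || any(adjacency > 1))
    stopf("tom_similarity: adjacency entries must be in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  den <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# first principal component of the standardized module submatrix, unit
# variance across samples, sign-oriented so its mean correlation with member
# genes is positive
.module_eigengene <- function(submat) {
  z <- t(scale(t(submat)))
  z[!is.finite(z)] <- 0
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  me <- pc$x[, 1]
  me <- me / stats::sd(me)
  if (mean(stats::cor(t(submat), me)) < 0) me <- -me
  me
}

#' Module detection on a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `dissTOM`, a static cut at the
#' 0.99 quantile of merge heights, small-cluster removal, eigengene-based
#' merging of close modules, and kME-based membership pruning.  Label 0
#' ("grey") marks unassigned genes.
#'
#' @param dissTOM dissimilarity matrix (1 - TOM).
#' @param expr expression matrix (same genes, features x samples) used for
#'   eigengenes and kME.
#' @param min_module_size minimum module size (default 50).
#' @param merge_cut_height eigengene dissimilarity (1 - cor) below which two
#'   modules merge (default 0.25).
#' @param kme_cutoff genes with |kME| to their own module below this are
#'   reassigned to grey (default 0.8).
#' @param cut_quantile quantile of merge heights for the static cut
#'   (default 0.99).
#' @return list with `labels` (integer per gene, 0 = grey), `eigengenes`
#'   (module x sample matrix), `kme` (gene x module matrix).
#' @export
detect_modules <- function(dissTOM, expr, min_module_size = 50,
                           merge_cut_height = 0.25, kme_cutoff = 0.8,
                           cut_quantile = 0.99) {
  n <- nrow(dissTOM)
  ids <- rownames(expr) %||% as.character(seq_len(n))
  if (n < min_module_size) {
    warning("fewer genes than min_module_size: single grey module")
    return(list(labels = stats::setNames(rep(0L, n), ids),
                eigengenes = NULL, kme = NULL))
  }
  hc <- stats::hclust(stats::as.dist(dissTOM), method = "average")
  cut_h <- stats::quantile(hc$height, cut_quantile)
  cl <- stats::cutree(hc, h = cut_h)

  # drop small clusters to grey (0), relabel survivors by decreasing size
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(n)
  ord <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- i

  # eigengene merge loop
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    mes <- vapply(mods, function(m)
      .module_eigengene(expr[labels == m, , drop = FALSE]),
      numeric(ncol(expr)))
    dd <- 1 - stats::cor(mes)
    diag(dd) <- Inf
    mn <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    if (dd[mn[1], mn[2]] >= merge_cut_height) break
    a <- mods[min(mn)]; b <- mods[max(mn)]
    labels[labels == b] <- a
    # compact labels
    mods <- sort(unique(labels[labels > 0]))
    labels <- match(labels, mods, nomatch = 0L)
    labels[is.na(labels)] <- 0L
  }

  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods))
    return(list(labels = stats::setNames(labels, ids),
                eigengenes = NULL, kme = NULL))
  mes <- vapply(mods, function(m)
    .module_eigengene(expr[labels == m, , drop = FALSE]),
    numeric(ncol(expr)))
  colnames(mes) <- paste0("ME", mods)
  kme <- stats::cor(t(expr), mes)
  rownames(kme) <- ids

  # membership pruning: |kME| to own module must reach the cutoff
  own <- kme[cbind(seq_len(n), match(labels, mods))]
  prune <- labels > 0 & abs(own) < kme_cutoff
  labels[prune] <- 0L

  list(labels = stats::setNames(labels, ids),
       eigengenes = t(mes), kme = kme)
}

#' Blockwise module detection for large gene sets
#'
#' Honors the maximum-block-size hint: gene sets up to `max_block_size` are
#' processed in one block (adjacency, TOM, [detect_modules()]); larger sets
#' are split by k-means pre-clustering on the standardized profiles, modules
#' are detected within each block, and modules whose eigengenes are nearly
#' identical across blocks are merged.
#'
#' @param expr expression matrix (genes x samples).
#' @param power soft-thresholding power.
#' @param max_block_size block size limit (default 5000).
#' @param ... passed to [detect_modules()].
#' @return as [detect_modules()]; `$tom` additionally holds the TOM when a
#'   single block was used (NULL otherwise).
#' @export
blockwise_modules <- function(expr, power, max_block_size = 5000, ...) {
  n <- nrow(expr)
  if (n <= max_block_size) {
    tom <- tom_similarity(adjacency_matrix(expr, power))
    out <- detect_modules(1 - tom, expr, ...)
    out$tom <- tom
    return(out)
  }
  n_blocks <- ceiling(n / max_block_size)
  z <- t(scale(t(expr)))
  z[!is.finite(z)] <- 0
  centers <- z[round(seq(1, n, length.out = n_blocks)), , drop = FALSE]
  km <- stats::kmeans(z, centers = centers, iter.max = 50)
  labels <- stats::setNames(integer(n), rownames(expr))
  kme_list <- list(); me_list <- list()
  offset <- 0L
  for (b in seq_len(n_blocks)) {
    idx <- which(km$cluster == b)
    sub <- expr[idx, , drop = FALSE]
    tom <- tom_similarity(adjacency_matrix(sub, power))
    mods <- detect_modules(1 - tom, sub, ...)
    lab <- mods$labels
    lab[lab > 0] <- lab[lab > 0] + offset
    labels[idx] <- lab
    if (!is.null(mods$eigengenes)) {
      rn <- as.integer(sub("ME", "", rownames(mods$eigengenes))) + offset
      rownames(mods$eigengenes) <- paste0("ME", rn)
      me_list[[b]] <- mods$eigengenes
    }
    offset <- max(c(offset, lab))
  }
  mes <- do.call(rbind, me_list)
  # merge near-identical modules across blocks
  if (!is.null(mes) && nrow(mes) > 1) {
    repeat {
      dd <- 1 - stats::cor(t(mes))
      diag(dd) <- Inf
      mn <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      if (dd[mn[1], mn[2]] >= 0.25) break
      a <- as.integer(sub("ME", "", rownames(mes)[min(mn)]))
      b <- as.integer(sub("ME", "", rownames(mes)[max(mn)]))
      labels[labels == b] <- a
      keep <- rownames(mes) != paste0("ME", b)
      mes <- mes[keep, , drop = FALSE]
      mes[paste0("ME", a), ] <- .module_eigengene(
        expr[labels == a, , drop = FALSE])
    }
  }
  mods_present <- sort(unique(labels[labels > 0]))
  relab <- match(labels, mods_present, nomatch = 0L)
  labels <- stats::setNames(as.integer(relab), names(labels))
  mes2 <- t(vapply(sort(unique(labels[labels > 0])), function(m)
    .module_eigengene(expr[labels == m, , drop = FALSE]),
    numeric(ncol(expr))))
  rownames(mes2) <- paste0("ME", sort(unique(labels[labels > 0])))
  kme <- stats::cor(t(expr), t(mes2))
  list(labels = labels, eigengenes = mes2, kme = kme, tom = NULL)
}

#' Module-trait correlation
#'
#' Pearson correlation between module eigengenes and trait indicators, with
#' p-values from the t transform.
#'
#' @param eigengenes module x sample matrix.
#' @param traits trait x sample matrix (e.g. one 0/1 indicator per design
#'   cell).
#' @return list with `cor` and `p` matrices (module x trait).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (ncol(eigengenes) != ncol(traits))
    stopf("eigengenes and traits must cover the same samples")
  sds <- apply(traits, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance trait(s): correlations undefined (NA)")
  r <- suppressWarnings(stats::cor(t(eigengenes), t(traits)))
  n <- ncol(eigengenes)
  p <- cor_pvalue(r, n)
  p[, sds == 0] <- NA_real_
  r[, sds == 0] <- NA_real_
  list(cor = r, p = p)
}

#' Gene significance (gene-trait correlation)
#' @param expr expression matrix (genes x samples).
#' @param trait numeric trait vector over samples.
#' @return named vector of Pearson correlations.
#' @export
gene_significance <- function(expr, trait) {
  drop(stats::cor(t(expr), trait))
}

#' Hub genes per module
#'
#' A gene is a hub when |kME to its own module| and |GS for the module's best
#' trait| both reach `cutoff`.
#'
#' @param labels module labels (0 = grey).
#' @param kme gene x module kME matrix (columns `ME<label>`).
#' @param expr expression matrix (genes x samples).
#' @param traits trait x sample matrix.
#' @param eigengenes module x sample matrix (to pick each module's best
#'   trait).
#' @param cutoff absolute-value cutoff (default 0.5).
#' @return data.frame with `gene_id`, `module`, `kme`, `best_trait`, `gs`,
#'   `hub`.
#' @export
find_hubs <- function(labels, kme, expr, traits, eigengenes, cutoff = 0.5) {
  mods <- sort(unique(labels[labels > 0]))
  out <- list()
  mt <- module_trait_correlation(eigengenes, traits)
  for (m in mods) {
    best_trait <- rownames(traits)[which.max(abs(mt$cor[paste0("ME", m), ]))]
    members <- names(labels)[labels == m]
    gk <- kme[members, paste0("ME", m)]
    gs <- gene_significance(expr[members, , drop = FALSE],
                            traits[best_trait, ])
    out[[length(out) + 1L]] <- data.frame(
      gene_id = members, module = m, kme = unname(gk),
      best_trait = best_trait, gs = unname(gs),
      hub = abs(gk) >= cutoff & abs(gs) >= cutoff,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), module = integer(0),
                      kme = numeric(0), best_trait = character(0),
                      gs = numeric(0), hub = logical(0)))
  do.call(rbind, out)
}

#' Export thresholded edges within a module
#'
#' @param weights TOM or adjacency matrix with gene dimnames.
#' @param labels module labels.
#' @param module module label to export.
#' @param weight_threshold minimum edge weight in \[0, 1\].
#' @param node_type optional named vector ("lncRNA"/"PCG") for endpoint
#'   annotation.
#' @return data.frame of undirected edges (`from`, `to`, `weight`,
#'   `from_type`, `to_type`), each pair once (from < to).
#' @export
export_edges <- function(weights, labels, module, weight_threshold,
                         node_type = NULL) {
  if (weight_threshold < 0 || weight_threshold > 1)
    stopf("export_edges: weight_threshold must be in [0, 1]")
  if (!module %in% labels)
    stopf("export_edges: unknown module label '%s'", module)
  members <- names(labels)[labels == module]
  sub <- weights[members, members, drop = FALSE]
  idx <- which(upper.tri(sub) & sub >= weight_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), from_type = character(0),
                      to_type = character(0)))
  typ <- function(g) if (is.null(node_type)) NA_character_ else
    unname(node_type[g])
  df <- data.frame(from = members[idx[, 1]], to = members[idx[, 2]],
                   weight = sub[idx], stringsAsFactors = FALSE)
  df$from_type <- typ(df$from); df$to_type <- typ(df$to)
  df[order(df$from, df$to), , drop = FALSE]
}
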