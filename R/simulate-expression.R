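# Expression-matrix generation with planted truth: log-normal replicate
# noise around per-condition means, planted treatment effects, genotype-
# dependent presence, per-condition module latents (module 1 tied to the
# root-sorbitol condition indicator), and cis-pair latents shared between a
# lncRNA and its partner PCG.

.sigma_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

# per-condition module latents: module 1 is the standardized root-sorbitol
# indicator; the rest are random profiles orthogonalised against the earlier
# ones (planted modules are distinct by construction, so chance correlation
# between latents cannot merge them downstream)
.module_latents <- function(nc, n_mod, indicator) {
  latents <- matrix(0, nc, n_mod)
  latents[, 1] <- as.numeric(scale(indicator))
  if (n_mod > 1) {
    for (m in 2:n_mod) {
      v <- stats::rnorm(nc)
      prev <- latents[, seq_len(m - 1), drop = FALSE]
      v <- v - prev %*% solve(crossprod(prev), crossprod(prev, v))
      latents[, m] <- as.numeric(scale(v))
    }
  }
  latents
}

#' Build the sample design table for a configuration
#' @param config a [sim_config()].
#' @return design data.frame (sample_id, genotype, tissue, treatment,
#'   replicate).
#' @export
sim_design <- function(config) {
  d <- expand.grid(replicate = seq_len(config$n_replicates),
                   treatment = config$treatments,
                   tissue = config$tissues,
                   genotype = config$genotypes,
                   stringsAsFactors = FALSE)
  d <- d[c("genotype", "tissue", "treatment", "replicate")]
  d$sample_id <- sprintf("%s_%s_%s_rep%d", d$genotype, d$tissue, d$treatment,
                         d$replicate)
  d[c("sample_id", "genotype", "tissue", "treatment", "replicate")]
}

#' Generate the FPKM matrix and expression truth tables
#'
#' @param config a [sim_config()].
#' @param tx_info data.frame with `transcript_id`, `kind`
#'   (`pcg`/`ref_nc`/`assembled`), `role`, `is_lncRNA`, `cis_partner`
#'   (partner transcript id or NA), `stress_activated` (treatment or NA).
#' @return list with `fpkm` (matrix), `design`, `truth` (list of `de`,
#'   `relatedness`, `modules`, `cis`).
#' @export
generate_expression <- function(config, tx_info) {
  set.seed(config$seed + 3L)
  design <- sim_design(config)
  ns <- nrow(design)
  cell <- paste(design$genotype, design$tissue, design$treatment, sep = ".")
  cells <- unique(cell)
  nc <- length(cells)
  cell_of <- match(cell, cells)
  cell_meta <- unique(data.frame(genotype = design$genotype,
                                 tissue = design$tissue,
                                 treatment = design$treatment,
                                 stringsAsFactors = FALSE))

  ids <- tx_info$transcript_id
  n <- length(ids)
  is_lnc <- tx_info$is_lncRNA
  kind <- tx_info$kind
  role <- tx_info$role

  # baselines (FPKM): PCGs span two decades; lncRNAs sit lower but above the
  # presence floor with margin; sub-threshold negatives start near zero
  baseline <- numeric(n)
  baseline[kind == "pcg"] <- 10^stats::runif(sum(kind == "pcg"), 0, 2)
  baseline[kind == "ref_nc"] <- 10^stats::runif(sum(kind == "ref_nc"), -0.2, 1)
  asm <- kind == "assembled"
  baseline[asm] <- 10^stats::runif(sum(asm), 0.4, 1.5)
  baseline[role == "neg_low_fpkm"] <- 0.08

  # per-condition effect matrix on the log2 scale
  eff <- matrix(0, n, nc)

  # --- module memberships ---------------------------------------------------
  cis_lnc <- which(role == "lnc_cis")
  cis_partner_ids <- tx_info$cis_partner[cis_lnc]
  cis_pcg <- match(cis_partner_ids, ids)
  pool_pcg <- which(kind == "pcg" & !(seq_len(n) %in% cis_pcg))
  n_mod <- config$n_modules
  msize <- config$module_size
  while (n_mod > 0 && n_mod * msize > length(pool_pcg)) n_mod <- n_mod - 1L
  module <- integer(n)
  if (n_mod > 0) {
    mod_genes <- sample(pool_pcg, n_mod * msize)
    module[mod_genes] <- rep(seq_len(n_mod), each = msize)
    root_sorb <- as.numeric(cell_meta$tissue == "root" &
                            cell_meta$treatment == "sorbitol")
    latents <- .module_latents(nc, n_mod, root_sorb)
    for (m in seq_len(n_mod))
      eff[module == m, ] <- eff[module == m, , drop = FALSE] +
        matrix(latents[, m], sum(module == m), nc, byrow = TRUE)
  }

  # --- cis-pair latents ------------------------------------------------------
  if (length(cis_lnc)) {
    for (i in seq_along(cis_lnc)) {
      u <- as.numeric(scale(stats::rnorm(nc)))
      eff[cis_lnc[i], ] <- eff[cis_lnc[i], ] + u
      eff[cis_pcg[i], ] <- eff[cis_pcg[i], ] + u
    }
  }

  # --- stress-activated lncRNAs ---------------------------------------------
  act <- which(!is.na(tx_info$stress_activated))
  de_truth <- list()
  for (i in act) {
    trt <- tx_info$stress_activated[i]
    eff[i, cell_meta$treatment == trt] <-
      eff[i, cell_meta$treatment == trt] + config$activated_log2fc
    for (ts in config$tissues)
      de_truth[[length(de_truth) + 1L]] <- data.frame(
        transcript_id = ids[i], tissue = ts, treatment = trt,
        direction = "up", effect = config$activated_log2fc,
        stress_activated = TRUE, stringsAsFactors = FALSE)
  }

  # --- planted DE sets -------------------------------------------------------
  # eligible: not module, not cis, not activated, not family
  elig <- which(module == 0 & !(seq_len(n) %in% c(cis_lnc, cis_pcg, act)) &
                role != "lnc_family" & role != "neg_low_fpkm" &
                kind != "ref_nc")
  taken <- integer(0)
  de_sets <- list()
  for (cname in names(config$de_frac)) {
    parts <- strsplit(cname, "_")[[1]]
    ts <- parts[1]; trt <- parts[2]
    n_de <- round(config$de_frac[[cname]] * n)
    # half of the NaCl sets re-use sorbitol transcripts (co-responsive)
    reuse <- character(0)
    if (trt == "NaCl" && !is.null(de_sets[[paste0(ts, "_sorbitol")]])) {
      prev <- de_sets[[paste0(ts, "_sorbitol")]]
      reuse <- prev$transcript_id[seq_len(min(nrow(prev), floor(n_de / 2)))]
    }
    n_new <- max(0L, n_de - length(reuse))
    avail <- setdiff(elig, taken)
    lnc_avail <- intersect(avail, which(is_lnc))
    n_lnc <- min(length(lnc_avail), max(1L, round(0.1 * n_new)))
    pick_lnc <- if (n_lnc > 0) sample(lnc_avail, n_lnc) else integer(0)
    pick_pcg <- sample(setdiff(avail, pick_lnc),
                       max(0L, n_new - n_lnc))
    picks <- c(pick_lnc, pick_pcg)
    taken <- c(taken, picks)
    up <- stats::runif(length(picks)) < ifelse(is_lnc[picks], 0.8, 0.5)
    sgn <- ifelse(up, 1, -1)
    sel_cells <- cell_meta$tissue == ts & cell_meta$treatment == trt
    for (k in seq_along(picks))
      eff[picks[k], sel_cells] <- eff[picks[k], sel_cells] +
        sgn[k] * config$effect_log2fc
    reuse_idx <- match(reuse, ids)
    if (length(reuse_idx)) {
      prev <- de_sets[[paste0(ts, "_sorbitol")]]
      rsgn <- ifelse(prev$direction[match(reuse, prev$transcript_id)] == "up", 1, -1)
      for (k in seq_along(reuse_idx))
        eff[reuse_idx[k], sel_cells] <- eff[reuse_idx[k], sel_cells] +
          rsgn[k] * config$effect_log2fc
    }
    df <- data.frame(
      transcript_id = c(ids[picks], reuse),
      tissue = ts, treatment = trt,
      direction = c(ifelse(up, "up", "down"),
                    if (length(reuse_idx)) ifelse(rsgn > 0, "up", "down")
                    else character(0)),
      effect = config$effect_log2fc, stress_activated = FALSE,
      stringsAsFactors = FALSE)
    de_sets[[cname]] <- df
    de_truth[[length(de_truth) + 1L]] <- df
  }

  # --- genotype relatedness --------------------------------------------------
  remaining <- setdiff(seq_len(n), c(which(module > 0), cis_lnc, cis_pcg, act,
                                     taken, which(role == "lnc_family")))
  lnc_rem <- intersect(remaining, which(is_lnc))
  pcg_rem <- intersect(remaining, which(kind == "pcg"))
  n_rel_lnc <- min(length(lnc_rem),
                   round(config$related_frac_lnc * sum(is_lnc)))
  n_rel_pcg <- min(length(pcg_rem),
                   round(config$related_frac_pcg * sum(kind == "pcg")))
  rel <- c(if (n_rel_lnc > 0) sample(lnc_rem, n_rel_lnc),
           if (n_rel_pcg > 0) sample(pcg_rem, n_rel_pcg))
  absent_genotype <- rep(NA_character_, n)
  if (length(rel)) {
    mut <- setdiff(config$genotypes, "WT")[1]
    absent_genotype[rel] <- ifelse(stats::runif(length(rel)) < 0.7, mut, "WT")
  }

  # --- assemble the matrix ---------------------------------------------------
  log2m <- matrix(log2(baseline), n, ns) + eff[, cell_of, drop = FALSE]
  sig <- .sigma_log2(config$noise_cv)
  if (sig > 0) log2m <- log2m + matrix(stats::rnorm(n * ns, sd = sig), n, ns)
  fpkm <- 2^log2m
  dimnames(fpkm) <- list(ids, design$sample_id)

  for (i in which(!is.na(absent_genotype)))
    fpkm[i, design$genotype == absent_genotype[i]] <- 0

  # margins: planted lncRNAs detectable (max >= 1); sub-threshold negatives
  # below the presence floor in every sample
  pos <- which(is_lnc)
  mx <- apply(fpkm[pos, , drop = FALSE], 1, max)
  fix <- mx < 1
  if (any(fix)) fpkm[pos[fix], ] <- fpkm[pos[fix], , drop = FALSE] * (1.5 / mx[fix])
  low <- which(role == "neg_low_fpkm")
  mx <- apply(fpkm[low, , drop = FALSE], 1, max)
  fix <- mx >= 0.5
  if (any(fix)) fpkm[low[fix], ] <- fpkm[low[fix], , drop = FALSE] * (0.4 / mx[fix])

  related_label <- ifelse(!is.na(absent_genotype), "related",
                   ifelse(role == "neg_low_fpkm", "undetected", "non-related"))

  truth <- list(
    de = if (length(de_truth)) do.call(rbind, de_truth) else
      data.frame(transcript_id = character(0), tissue = character(0),
                 treatment = character(0), direction = character(0),
                 effect = numeric(0), stress_activated = logical(0)),
    relatedness = data.frame(transcript_id = ids, label = related_label,
                             absent_genotype = absent_genotype,
                             stringsAsFactors = FALSE),
    modules = data.frame(transcript_id = ids, module = module,
                         stringsAsFactors = FALSE),
    cis = data.frame(lncrna_id = ids[cis_lnc], pcg_id = ids[cis_pcg],
                     stringsAsFactors = FALSE))
  list(fpkm = fpkm, design = design, truth = truth)
}

#' Simulate a stand-alone DE calibration matrix
#'
#' A minimal fixture for testing the differential-expression stage: `n`
#' transcripts with log-normal replicate noise, the first `n_planted`
#' carrying a planted log2 effect (alternating sign) in the treated cell.
#'
#' @param n transcripts.
#' @param n_planted planted DE transcripts (0 for a null matrix).
#' @param log2fc planted effect size.
#' @param noise_cv replicate CV.
#' @param n_rep replicates per cell.
#' @param seed RNG seed.
#' @return list with `fpkm` (columns treated/control), `design`,
#'   `planted` (ids), `direction`.
#' @export
simulate_de_matrix <- function(n, n_planted = 0, log2fc = 2, noise_cv = 0.3,
                               n_rep = 2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%05d", seq_len(n))
  baseline <- 10^stats::runif(n, 0, 2)
  sgn <- rep_len(c(1, -1), n_planted)
  eff_trt <- c(sgn * log2fc, rep(0, n - n_planted))
  sig <- .sigma_log2(noise_cv)
  mk <- function(shift) {
    m <- matrix(log2(baseline) + shift, n, n_rep)
    if (sig > 0) m <- m + matrix(stats::rnorm(n * n_rep, sd = sig), n, n_rep)
    2^m
  }
  fpkm <- cbind(mk(eff_trt), mk(0))
  colnames(fpkm) <- c(sprintf("WT_root_sorbitol_rep%d", seq_len(n_rep)),
                      sprintf("WT_root_control_rep%d", seq_len(n_rep)))
  rownames(fpkm) <- ids
  design <- data.frame(
    sample_id = colnames(fpkm),
    genotype = "WT", tissue = "root",
    treatment = rep(c("sorbitol", "control"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2), stringsAsFactors = FALSE)
  list(fpkm = fpkm, design = design,
       planted = ids[seq_len(n_planted)],
       direction = if (n_planted) ifelse(sgn > 0, "up", "down") else character(0))
}

#' Simulate a planted-module expression matrix
#'
#' Generates `n_modules` blocks of `module_size` genes, each driven by a
#' shared per-condition latent (module 1 tied to the root-sorbitol
#' indicator), plus independent log-normal replicate noise - the fixture
#' used to validate module detection.
#'
#' @param config a [sim_config()] (module, design and noise settings are
#'   read from it).
#' @return list with `fpkm`, `design`, `labels` (planted module per gene),
#'   `trait` (the root-sorbitol indicator over samples).
#' @export
simulate_module_matrix <- function(config) {
  set.seed(config$seed + 7L)
  design <- sim_design(config)
  cell <- paste(design$genotype, design$tissue, design$treatment, sep = ".")
  cells <- unique(cell)
  nc <- length(cells)
  cell_of <- match(cell, cells)
  cell_meta <- unique(data.frame(tissue = design$tissue,
                                 treatment = design$treatment,
                                 stringsAsFactors = FALSE))
  n_mod <- config$n_modules
  n <- n_mod * config$module_size
  ids <- sprintf("G%04d", seq_len(n))
  labels <- rep(seq_len(n_mod), each = config$module_size)
  root_sorb <- as.numeric(cell_meta$tissue == "root" &
                          cell_meta$treatment == "sorbitol")
  latents <- .module_latents(nc, n_mod, root_sorb)
  baseline <- 10^stats::runif(n, 0.5, 1.5)
  log2m <- matrix(log2(baseline), n, nrow(design)) +
    t(latents[cell_of, labels])
  sig <- .sigma_log2(config$noise_cv)
  if (sig > 0)
    log2m <- log2m + matrix(stats::rnorm(length(log2m), sd = sig), nrow(log2m))
  fpkm <- 2^log2m
  dimnames(fpkm) <- list(ids, design$sample_id)
  trait <- as.numeric(design$tissue == "root" & design$treatment == "sorbitol")
  list(fpkm = fpkm, design = design, labels = stats::setNames(labels, ids),
       trait = trait)
}
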