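# Synthetic multi-tissue FPKM generator with planted ground-truth gene
# classes (housekeeping, reference, tissue-specific, sex-dominated, silent),
# ERCC spike-in reference/spiking, and a synthetic homology mapping.

#' Default 17-tissue panel
#'
#' Thirteen non-sexual tissues plus ovary and uterus (female only) and testis
#' and vesicular gland (male only).
#'
#' @return data.frame with columns `tissue`, `sexual`, `sex` (`NA` for
#'   non-sexual tissues).
#' @export
default_tissues <- function() {
  nonsex <- c("adrenal_gland", "brain", "forestomach", "heart", "kidney",
              "large_intestine", "liver", "lung", "muscle", "small_intestine",
              "spleen", "stomach", "thymus")
  data.frame(
    tissue = c(nonsex, "ovary", "uterus", "testis", "vesicular_gland"),
    sexual = c(rep(FALSE, length(nonsex)), TRUE, TRUE, TRUE, TRUE),
    sex = c(rep(NA_character_, length(nonsex)),
            "female", "female", "male", "male"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes the synthetic world: a 17-tissue, two-sex, four-individual body
#' map with 68 samples by default (eight brain and liver samples, four
#' kidney, two testis, four of each remaining non-sexual tissue split evenly
#' between the sexes, and two of each single-sex tissue). Expression is
#' lognormal: `FPKM = 2^(mu_g + tau_{g,tissue} + s_{g,sex} + e)` with
#' `e ~ N(0, replicate_noise_sd_log2)`; silent genes are exact zeros.
#'
#' Planted classes realise their configured effect sizes in expectation:
#' tissue-specific genes are elevated by `log2(ts_fold)` in one tissue,
#' sex-dominated genes by `log2(sex_fold)` in one sex of one non-sexual
#' tissue, housekeeping/reference genes draw small per-tissue effects
#' (`hk_tissue_sd_log2` / `ref_tissue_sd_log2`). Background genes draw
#' per-tissue effects with SD `tissue_effect_sd_log2`, with the largest
#' effect tied to the second largest so that no background gene is specific
#' to a single tissue — the planted classes are then the only genes that can
#' meet the housekeeping or tissue-specific definitions.
#'
#' @param n_genes Total genes.
#' @param tissues Tissue panel as from [default_tissues()].
#' @param samples_per_tissue `NULL` for the default 68-sample design, a
#'   single integer for a uniform design, or a named integer vector.
#' @param biotype_proportions Named proportions over the four biotype groups.
#' @param frac_silent Scalar fraction of exactly-zero genes, or a named
#'   per-biotype-group vector (default mirrors the complementary
#'   expressed/silent pattern of coding vs non-coding genes).
#' @param n_housekeeping,n_reference Planted stable genes (reference genes
#'   are the highly-expressed, extra-stable tier).
#' @param hk_mean_log2_range,ref_mean_log2_range Uniform ranges for planted
#'   mean log2 FPKM.
#' @param hk_tissue_sd_log2,ref_tissue_sd_log2 Per-tissue effect SDs of the
#'   planted stable classes.
#' @param n_tissue_specific Planted tissue-specific genes per tissue.
#' @param ts_fold Planted tissue-specific fold (linear scale).
#' @param ts_mean_log2_range Uniform range for the non-target mean of planted
#'   tissue-specific and sex-dominated genes.
#' @param n_sex_dominated Planted sex-dominated genes per non-sexual tissue
#'   (dominant sex alternates).
#' @param sex_fold Planted sex-dominated fold.
#' @param baseline_log2_mean,baseline_log2_sd Background gene mean law.
#' @param tissue_effect_sd_log2 Background per-tissue effect SD.
#' @param replicate_noise_sd_log2 Replicate noise SD on the log2 scale.
#' @param ercc_fraction Nominal spike-in share of each sample's total signal.
#' @param seed Integer seed; identical (config, seed) gives bit-identical
#'   output.
#' @return list of class `bm_sim_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              tissues = default_tissues(),
                              samples_per_tissue = NULL,
                              biotype_proportions = c(protein_coding = 0.51,
                                                      ncRNA = 0.20,
                                                      pseudogene = 0.18,
                                                      other = 0.11),
                              frac_silent = c(protein_coding = 0.08,
                                              ncRNA = 0.66,
                                              pseudogene = 0.47,
                                              other = 0.14),
                              n_housekeeping = 200L,
                              n_reference = 30L,
                              hk_mean_log2_range = c(2.5, 7),
                              ref_mean_log2_range = c(7, 9),
                              hk_tissue_sd_log2 = 0.3,
                              ref_tissue_sd_log2 = 0.15,
                              n_tissue_specific = 20L,
                              ts_fold = 16,
                              ts_mean_log2_range = c(2, 5),
                              n_sex_dominated = 6L,
                              sex_fold = 4,
                              baseline_log2_mean = 2,
                              baseline_log2_sd = 2,
                              tissue_effect_sd_log2 = 2,
                              replicate_noise_sd_log2 = 0.25,
                              ercc_fraction = 0.01,
                              seed = 1L) {
  stopifnot(is_count(n_genes), n_genes > 0,
            all(c("tissue", "sexual", "sex") %in% names(tissues)),
            is_count(n_housekeeping), is_count(n_reference),
            is_count(n_tissue_specific), is_count(n_sex_dominated),
            ts_fold > 0, sex_fold > 0,
            hk_tissue_sd_log2 >= 0, ref_tissue_sd_log2 >= 0,
            tissue_effect_sd_log2 >= 0, replicate_noise_sd_log2 >= 0,
            ercc_fraction > 0, ercc_fraction < 1)
  if (abs(sum(biotype_proportions) - 1) > 1e-8) {
    stopf("biotype_proportions must sum to 1")
  }
  if (any(frac_silent < 0) || any(frac_silent >= 1)) {
    stopf("frac_silent must lie in [0, 1)")
  }
  if (length(frac_silent) > 1L &&
      !setequal(names(frac_silent), BIOTYPE_GROUPS)) {
    stopf("per-biotype frac_silent must name all four biotype groups")
  }
  cfg <- list(n_genes = as.integer(n_genes), tissues = tissues,
              samples_per_tissue = samples_per_tissue,
              biotype_proportions = biotype_proportions[BIOTYPE_GROUPS],
              frac_silent = frac_silent,
              n_housekeeping = as.integer(n_housekeeping),
              n_reference = as.integer(n_reference),
              hk_mean_log2_range = hk_mean_log2_range,
              ref_mean_log2_range = ref_mean_log2_range,
              hk_tissue_sd_log2 = hk_tissue_sd_log2,
              ref_tissue_sd_log2 = ref_tissue_sd_log2,
              n_tissue_specific = as.integer(n_tissue_specific),
              ts_fold = ts_fold,
              ts_mean_log2_range = ts_mean_log2_range,
              n_sex_dominated = as.integer(n_sex_dominated),
              sex_fold = sex_fold,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              tissue_effect_sd_log2 = tissue_effect_sd_log2,
              replicate_noise_sd_log2 = replicate_noise_sd_log2,
              ercc_fraction = ercc_fraction,
              seed = as.integer(seed))
  structure(cfg, class = "bm_sim_config")
}

# Sample sheet for the configured design.
build_sample_sheet <- function(cfg) {
  td <- cfg$tissues
  mice <- data.frame(individual = paste0("mouse", 1:4),
                     sex = c("male", "male", "female", "female"),
                     stringsAsFactors = FALSE)
  rows <- list()
  spt <- cfg$samples_per_tissue
  for (i in seq_len(nrow(td))) {
    t <- td$tissue[i]
    eligible <- if (td$sexual[i]) mice[mice$sex == td$sex[i], ] else mice
    # interleave sexes for non-sexual tissues: mouse1(M), mouse3(F), ...
    if (!td$sexual[i]) eligible <- eligible[c(1L, 3L, 2L, 4L), ]
    n <- if (is.null(spt)) {
      if (t %in% c("brain", "liver")) 8L
      else if (t == "kidney") 4L
      else if (t == "testis") 2L
      else if (td$sexual[i]) 2L
      else 4L
    } else if (length(spt) == 1L && is.null(names(spt))) {
      as.integer(spt)
    } else {
      if (!t %in% names(spt)) stopf("samples_per_tissue lacks tissue '%s'", t)
      as.integer(spt[[t]])
    }
    idx <- rep(seq_len(nrow(eligible)), length.out = n)
    rep_no <- stats::ave(idx, idx, FUN = seq_along)
    rows[[t]] <- data.frame(
      sample_id = sprintf("%s_%s_r%d", t, eligible$individual[idx], rep_no),
      tissue = t, sex = eligible$sex[idx],
      individual = eligible$individual[idx],
      sexual_tissue = td$sexual[i], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact integer partition of n by proportions p (largest-remainder method).
partition_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    up <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[up] <- base[up] + 1
  }
  as.integer(base)
}

#' Generate a synthetic body-map dataset with planted truth
#'
#' @param config A [simulation_config()].
#' @return list of class `bm_sim_dataset` with elements `matrix` (FPKM),
#'   `annotation`, `metadata`, `truth` (gene_id, class, target_tissue,
#'   target_sex, effect_log2), `expected_tissue_log2` (gene x tissue true
#'   mean log2 FPKM before sex effects and noise; `-Inf` for silent genes)
#'   and `config`.
#' @export
generate_dataset <- function(config = simulation_config()) {
  cfg <- config
  meta <- build_sample_sheet(cfg)
  tissues <- cfg$tissues$tissue
  nonsexual <- cfg$tissues$tissue[!cfg$tissues$sexual]
  ng <- cfg$n_genes
  nt <- length(tissues)

  # gene budget (silent counts are deterministic given biotype counts)
  bio_counts <- partition_counts(ng, cfg$biotype_proportions)
  names(bio_counts) <- names(cfg$biotype_proportions)
  fs <- cfg$frac_silent
  n_silent_by_bio <- if (length(fs) == 1L) {
    partition_counts(round(fs * ng), bio_counts)
  } else {
    as.integer(round(fs[names(bio_counts)] * bio_counts))
  }
  names(n_silent_by_bio) <- names(bio_counts)
  n_planted <- cfg$n_housekeeping + cfg$n_reference +
    nt * cfg$n_tissue_specific + length(nonsexual) * cfg$n_sex_dominated
  if (n_planted + sum(n_silent_by_bio) > ng) {
    stopf("gene budget over-committed: %d planted + %d silent > %d genes",
          n_planted, sum(n_silent_by_bio), ng)
  }
  if (n_planted + n_silent_by_bio[["protein_coding"]] > bio_counts[["protein_coding"]]) {
    stopf("planted classes (%d, all protein_coding) exceed the protein_coding budget",
          n_planted)
  }

  withr::with_seed(cfg$seed, {
    gene_id <- sprintf("GENE%05d", seq_len(ng))
    biotype <- sample(rep(names(bio_counts), bio_counts))
    chrom_pool <- c(paste0("chr", 1:19), "chrX", "chrY")
    chromosome <- sample(chrom_pool, ng, replace = TRUE,
                         prob = c(rep(1, 19), 0.5, 0.05))

    class <- rep("background", ng)
    target_tissue <- rep(NA_character_, ng)
    target_sex <- rep(NA_character_, ng)
    effect_log2 <- rep(0, ng)

    pcg_pool <- which(biotype == "protein_coding")
    take <- function(n) {
      picked <- sample(pcg_pool, n)
      pcg_pool <<- setdiff(pcg_pool, picked)
      picked
    }
    idx_hk <- take(cfg$n_housekeeping)
    idx_ref <- take(cfg$n_reference)
    class[idx_hk] <- "housekeeping"
    class[idx_ref] <- "reference"
    idx_ts <- integer(0)
    for (t in tissues) {
      i <- take(cfg$n_tissue_specific)
      class[i] <- "tissue_specific"
      target_tissue[i] <- t
      effect_log2[i] <- log2(cfg$ts_fold)
      idx_ts <- c(idx_ts, i)
    }
    idx_sex <- integer(0)
    for (k in seq_along(nonsexual)) {
      i <- take(cfg$n_sex_dominated)
      class[i] <- "sex_dominated"
      target_tissue[i] <- nonsexual[k]
      first <- if (k %% 2 == 1L) c("female", "male") else c("male", "female")
      target_sex[i] <- rep(first, length.out = cfg$n_sex_dominated)
      effect_log2[i] <- log2(cfg$sex_fold)
      idx_sex <- c(idx_sex, i)
    }
    # silent genes drawn from the remaining background of each biotype
    idx_silent <- integer(0)
    for (b in names(bio_counts)) {
      pool <- which(biotype == b & class == "background")
      n_s <- n_silent_by_bio[[b]]
      if (n_s > length(pool)) {
        stopf("silent budget for biotype '%s' (%d) exceeds free genes (%d)",
              b, n_s, length(pool))
      }
      i <- if (n_s > 0) sample(pool, n_s) else integer(0)
      class[i] <- "silent"
      idx_silent <- c(idx_silent, i)
    }

    # expected per-tissue mean log2 FPKM
    E <- matrix(0, ng, nt, dimnames = list(gene_id, tissues))
    # capped tissue effects: the top effect is tied to the runner-up so no
    # non-planted profile is single-tissue specific by construction
    capped_tau <- function(n) {
      tau <- matrix(rnorm(n * nt, 0, cfg$tissue_effect_sd_log2), n, nt)
      if (nt >= 2L) {
        tau <- t(apply(tau, 1L, function(x) {
          o <- order(x, decreasing = TRUE)[1:2]
          x[o[1L]] <- x[o[2L]]
          x
        }))
      }
      tau
    }
    idx_bg <- which(class == "background")
    mu <- rnorm(length(idx_bg), cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    E[idx_bg, ] <- mu + capped_tau(length(idx_bg))

    plant_stable <- function(idx, mean_range, tissue_sd) {
      mu <- runif(length(idx), mean_range[1L], mean_range[2L])
      mu + matrix(rnorm(length(idx) * nt, 0, tissue_sd), length(idx), nt)
    }
    if (length(idx_hk)) E[idx_hk, ] <- plant_stable(idx_hk, cfg$hk_mean_log2_range,
                                                    cfg$hk_tissue_sd_log2)
    if (length(idx_ref)) E[idx_ref, ] <- plant_stable(idx_ref, cfg$ref_mean_log2_range,
                                                      cfg$ref_tissue_sd_log2)
    for (i in idx_ts) {
      mu <- runif(1L, cfg$ts_mean_log2_range[1L], cfg$ts_mean_log2_range[2L])
      E[i, ] <- mu
      E[i, target_tissue[i]] <- mu + log2(cfg$ts_fold)
    }
    # sex-dominated genes ride on an ordinary tissue profile; the planted
    # sex effect is added at the sample level below
    if (length(idx_sex)) {
      mu_sex <- runif(length(idx_sex), cfg$ts_mean_log2_range[1L],
                      cfg$ts_mean_log2_range[2L])
      E[idx_sex, ] <- mu_sex + capped_tau(length(idx_sex))
    }
    E[idx_silent, ] <- -Inf

    # realize samples
    ns <- nrow(meta)
    logv <- E[, meta$tissue, drop = FALSE] +
      matrix(rnorm(ng * ns, 0, cfg$replicate_noise_sd_log2), ng, ns)
    # sex effect: planted dominant sex of the target tissue
    for (i in idx_sex) {
      hit <- meta$tissue == target_tissue[i] & meta$sex == target_sex[i]
      logv[i, hit] <- logv[i, hit] + log2(cfg$sex_fold)
    }
    values <- 2^logv
    values[class == "silent", ] <- 0
    dimnames(values) <- list(gene_id, meta$sample_id)

    annotation <- gene_annotation(data.frame(
      gene_id = gene_id, symbol = paste0("Sym", seq_len(ng)),
      biotype = biotype, chromosome = chromosome, stringsAsFactors = FALSE))
    truth <- data.frame(gene_id = gene_id, class = class,
                        target_tissue = target_tissue, target_sex = target_sex,
                        effect_log2 = effect_log2, stringsAsFactors = FALSE)
    structure(list(matrix = expression_matrix(values),
                   annotation = annotation,
                   metadata = sample_metadata(meta),
                   truth = truth,
                   expected_tissue_log2 = E,
                   config = cfg),
              class = "bm_sim_dataset")
  })
}

#' Generate a synthetic ERCC-style spike-in reference table
#'
#' Mirrors the shape of the real External RNA Controls Consortium design — 92
#' spikes split into four Mix1:Mix2 ratio groups (4:1, 1:1, 2:3, 1:2) of 23
#' spikes each, spanning at least a 2^18 concentration range — but every
#' concentration is generated, not copied from the vendor table.
#'
#' @param seed Integer seed.
#' @return data.frame with `spike_id`, `mix1_concentration`,
#'   `mix2_concentration` (attomol/ul) and `ratio_group`.
#' @export
generate_ercc_reference <- function(seed = 1L) {
  groups <- c("4:1", "1:1", "2:3", "1:2")
  mix2_factor <- c("4:1" = 0.25, "1:1" = 1, "2:3" = 1.5, "1:2" = 2)
  withr::with_seed(as.integer(seed), {
    grp <- sample(rep(groups, each = 23L))
    ladder <- 2^seq(-3, 18, length.out = 23L)
    mix1 <- numeric(92L)
    for (g in groups) {
      idx <- which(grp == g)
      mix1[idx] <- ladder[sample.int(23L)] * 2^rnorm(23L, 0, 0.2)
    }
    ref <- data.frame(spike_id = sprintf("ERCC-%05d", seq_len(92L)),
                      mix1_concentration = mix1,
                      mix2_concentration = mix1 * mix2_factor[grp],
                      ratio_group = grp, stringsAsFactors = FALSE)
    stopifnot(max(ref$mix1_concentration) / min(ref$mix1_concentration) >= 2^18)
    ref
  })
}

#' Append synthetic ERCC spike-in rows to an FPKM matrix
#'
#' Spike FPKM is proportional to the assigned mix's concentration times
#' lognormal noise, rescaled per sample so that the spike signal is
#' `ercc_fraction` of the sample's total FPKM. Per-sample overrides simulate
#' a missing spike-in (all-zero spike rows) or degradation (inflated
#' fraction).
#'
#' @param matrix FPKM matrix without spike rows.
#' @param ref Reference table from [generate_ercc_reference()].
#' @param mix_assignment Named character vector `sample_id -> "Mix1"|"Mix2"`.
#' @param noise_sd_log2 Lognormal noise SD (0 gives exact proportionality).
#' @param seed Integer seed.
#' @param ercc_fraction Target spike share of each sample's total.
#' @param override Optional named list: `"missing"` zeroes a sample's spikes,
#'   a number replaces its target fraction.
#' @return FPKM matrix with 92 additional `ERCC-*` rows.
#' @export
spike_dataset <- function(matrix, ref, mix_assignment, noise_sd_log2 = 0,
                          seed = 1L, ercc_fraction = 0.01, override = NULL) {
  if (any(grepl("^ERCC-", rownames(matrix)))) {
    stopf("matrix already contains ERCC rows")
  }
  missing_assign <- setdiff(colnames(matrix), names(mix_assignment))
  if (length(missing_assign)) {
    stopf("sample(s) without a mix assignment: %s", fmt_ids(missing_assign))
  }
  bad <- setdiff(unique(mix_assignment[colnames(matrix)]), c("Mix1", "Mix2"))
  if (length(bad)) stopf("mix assignment must be 'Mix1' or 'Mix2', found: %s",
                         fmt_ids(bad))
  withr::with_seed(as.integer(seed), {
    spikes <- base::matrix(0, nrow(ref), ncol(matrix),
                           dimnames = list(ref$spike_id, colnames(matrix)))
    for (s in colnames(matrix)) {
      ov <- override[[s]]
      if (identical(ov, "missing")) next
      f <- if (is.numeric(ov)) ov else ercc_fraction
      conc <- if (mix_assignment[[s]] == "Mix1") ref$mix1_concentration
              else ref$mix2_concentration
      raw <- conc * 2^rnorm(nrow(ref), 0, noise_sd_log2)
      total <- sum(matrix[, s])
      spikes[, s] <- raw * (f / (1 - f)) * total / sum(raw)
    }
    rbind(matrix, spikes)
  })
}

#' Generate a synthetic cross-species homology mapping and foreign
#' housekeeping list
#'
#' Builds a one-to-one mapping from every simulated gene to a synthetic
#' "foreign" (human-like) id, and a foreign housekeeping list whose mapped
#' genes share `overlap_fraction` of its members with the planted
#' housekeeping/reference set.
#'
#' @param truth Truth table from [generate_dataset()].
#' @param n_foreign_hk Size of the foreign housekeeping list.
#' @param overlap_fraction Fraction of the foreign list that maps into the
#'   planted housekeeping set.
#' @param seed Integer seed.
#' @param prefix Foreign id prefix.
#' @return list with `mapping` (data.frame `gene_id`, `foreign_id`) and
#'   `foreign_hk` (character vector of foreign ids).
#' @export
generate_homology <- function(truth, n_foreign_hk, overlap_fraction,
                              seed = 1L, prefix = "FOR") {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  mapping <- data.frame(gene_id = truth$gene_id,
                        foreign_id = paste0(prefix, "_", truth$gene_id),
                        stringsAsFactors = FALSE)
  hk <- truth$gene_id[truth$class %in% c("housekeeping", "reference")]
  other <- truth$gene_id[!truth$class %in% c("housekeeping", "reference", "silent")]
  n_in <- round(overlap_fraction * n_foreign_hk)
  if (n_in > length(hk)) {
    stopf("requested overlap (%d) exceeds planted housekeeping genes (%d)",
          n_in, length(hk))
  }
  if (n_foreign_hk - n_in > length(other)) {
    stopf("n_foreign_hk exceeds mappable genes")
  }
  withr::with_seed(as.integer(seed), {
    chosen <- c(sample(hk, n_in), sample(other, n_foreign_hk - n_in))
  })
  list(mapping = mapping,
       foreign_hk = mapping$foreign_id[match(chosen, mapping$gene_id)])
}
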