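test_that("generation is deterministic under a fixed seed", {
  a <- generate_dataset(small_sim_config(seed = 42))
  b <- generate_dataset(small_sim_config(seed = 42))
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotation, b$annotation)
  c <- generate_dataset(small_sim_config(seed = 43))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("scalar silent fraction plants exactly the configured zero rows", {
  cfg <- simulation_config(n_genes = 1000L, frac_silent = 0.1,
                           n_housekeeping = 50L, n_reference = 5L,
                           n_tissue_specific = 2L, n_sex_dominated = 1L,
                           seed = 5)
  sim <- generate_dataset(cfg)
  zero_rows <- rownames(sim$matrix)[rowSums(sim$matrix != 0) == 0]
  expect_length(zero_rows, 100)
  expect_setequal(zero_rows, sim$truth$gene_id[sim$truth$class == "silent"])
})

test_that("planted class counts match the configuration", {
  sim <- generate_dataset(simulation_config(n_genes = 2000L,
                                            n_tissue_specific = 20L, seed = 2))
  tab <- table(sim$truth$class)
  expect_equal(unname(tab["tissue_specific"]), 20L * 17L)
  expect_equal(unname(tab["housekeeping"]), 200L)
  expect_equal(unname(tab["reference"]), 30L)
  # one target tissue per planted gene, every tissue covered
  ts <- sim$truth[sim$truth$class == "tissue_specific", ]
  expect_equal(sort(unique(ts$target_tissue)), sort(default_tissues()$tissue))
  # classes are mutually exclusive by construction (one label per gene)
  expect_equal(nrow(sim$truth), 2000L)
})

test_that("over-committed gene budgets fail before sampling", {
  expect_error(
    generate_dataset(simulation_config(n_genes = 300L, n_housekeeping = 200L,
                                       n_tissue_specific = 20L)),
    "budget")
})

test_that("planted tissue-specific effects are realized in expectation", {
  for (seed in c(11, 12, 13)) {
    sim <- generate_dataset(small_sim_config(seed = seed))
    E <- sim$expected_tissue_log2
    ts <- sim$truth[sim$truth$class == "tissue_specific", ]
    gap <- vapply(seq_len(nrow(ts)), function(i) {
      row <- E[ts$gene_id[i], ]
      row[ts$target_tissue[i]] - max(row[names(row) != ts$target_tissue[i]])
    }, numeric(1))
    expect_lt(abs(mean(gap) - log2(16)) / log2(16), 0.05)
  }
})

test_that("planted reference genes satisfy the reference criteria", {
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    sim <- generate_dataset(small_sim_config(seed = seed))
    st <- stability_stats(sim$matrix, sim$metadata)
    rf <- select_reference_genes(st, analysis_config())
    planted <- sim$truth$gene_id[sim$truth$class == "reference"]
    hits <- hits + sum(planted %in% rf$genes)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.99)
})

test_that("ERCC reference has the canonical group structure", {
  ref <- generate_ercc_reference(seed = 1)
  expect_equal(nrow(ref), 92)
  expect_equal(unname(table(ref$ratio_group)[c("4:1", "1:1", "2:3", "1:2")]),
               rep(23L, 4), ignore_attr = TRUE)
  nominal <- c("4:1" = 4, "1:1" = 1, "2:3" = 2 / 3, "1:2" = 0.5)
  expect_equal(ref$mix1_concentration / ref$mix2_concentration,
               unname(nominal[ref$ratio_group]))
  expect_gte(max(ref$mix1_concentration) / min(ref$mix1_concentration), 2^18)
  expect_true(all(ref$mix1_concentration > 0 & ref$mix2_concentration > 0))
  expect_identical(ref, generate_ercc_reference(seed = 1))
})

test_that("spiking scales to the target fraction and honours overrides", {
  sim <- generate_dataset(small_sim_config(seed = 8))
  ref <- generate_ercc_reference(seed = 8)
  mix <- setNames(rep(c("Mix1", "Mix2"), length.out = ncol(sim$matrix)),
                  colnames(sim$matrix))
  s1 <- colnames(sim$matrix)[1]
  spiked <- spike_dataset(sim$matrix, ref, mix, noise_sd_log2 = 0, seed = 8,
                          override = setNames(list("missing"), s1))
  spikes <- spiked[grep("^ERCC-", rownames(spiked)), ]
  expect_true(all(spikes[, s1] == 0))
  for (s in colnames(spiked)[2:4]) {
    expect_equal(sum(spikes[, s]) / sum(spiked[, s]), 0.01, tolerance = 1e-12)
    # zero noise: spike FPKM exactly proportional to assigned concentration
    conc <- if (mix[[s]] == "Mix1") ref$mix1_concentration else ref$mix2_concentration
    expect_equal(stats::cor(spikes[, s], conc), 1, tolerance = 1e-12)
  }
  expect_error(spike_dataset(spiked, ref, mix), "already contains")
  expect_error(spike_dataset(sim$matrix, ref, mix[-1]), "without a mix")
})

test_that("homology generator hits the requested overlap exactly", {
  sim <- generate_dataset(small_sim_config(seed = 4))
  planted <- sim$truth$gene_id[sim$truth$class %in% c("housekeeping", "reference")]

  h0 <- generate_homology(sim$truth, n_foreign_hk = 40, overlap_fraction = 0,
                          seed = 3)
  ov0 <- homology_overlap(planted, h0$foreign_hk, h0$mapping)
  expect_equal(ov0$overlap, 0)

  h1 <- generate_homology(sim$truth, n_foreign_hk = length(planted),
                          overlap_fraction = 1, seed = 3)
  ov1 <- homology_overlap(planted, h1$foreign_hk, h1$mapping)
  expect_equal(ov1$overlap, length(planted))

  hf <- generate_homology(sim$truth, n_foreign_hk = 60,
                          overlap_fraction = 0.744, seed = 3)
  # brute-force set intersection through the mapping
  mapped_back <- hf$mapping$gene_id[match(hf$foreign_hk, hf$mapping$foreign_id)]
  expect_equal(length(intersect(mapped_back, planted)), round(0.744 * 60))

  expect_error(generate_homology(sim$truth, n_foreign_hk = 100,
                                 overlap_fraction = 1, seed = 1),
               "exceeds")
})

test_that("default design reproduces the 68-sample body-map layout", {
  meta <- generate_dataset(small_sim_config(seed = 1))$metadata
  expect_equal(nrow(meta), 68)
  expect_equal(length(unique(meta$tissue)), 17)
  sizes <- table(meta$tissue)
  expect_equal(unname(sizes[c("brain", "liver", "kidney", "testis", "ovary")]),
               c(8L, 8L, 4L, 2L, 2L), ignore_attr = TRUE)
  # sexual tissues in exactly one sex; non-sexual in both
  sex_by_tissue <- tapply(meta$sex, meta$tissue, function(s) length(unique(s)))
  expect_true(all(sex_by_tissue[c("ovary", "uterus", "testis", "vesicular_gland")] == 1))
  expect_true(all(sex_by_tissue[setdiff(names(sex_by_tissue),
                                        c("ovary", "uterus", "testis",
                                          "vesicular_gland"))] == 2))
  # uniform override
  meta2 <- generate_dataset(small_sim_config(seed = 1,
                                             samples_per_tissue = 2))$metadata
  expect_equal(nrow(meta2), 34)
})
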