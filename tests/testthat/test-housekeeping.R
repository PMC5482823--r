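four_sample_meta <- function(cols, tissues) {
  sample_metadata(data.frame(sample_id = cols, tissue = tissues,
                             sex = "female", individual = "m1"))
}

test_that("stability statistics match hand arithmetic", {
  m <- rbind(const8 = rep(8, 4), spread = c(4, 4, 64, 64), haszero = c(0, 1, 2, 3))
  colnames(m) <- paste0("s", 1:4)
  meta <- four_sample_meta(colnames(m), rep(c("A", "B"), each = 2))
  st <- stability_stats(m, meta)
  i <- match("const8", st$gene_id)
  expect_equal(st$min_sample_fpkm[i], 8)
  expect_equal(st$sd_across_tissues[i], 0)
  expect_equal(st$max_abs_dev[i], 0)
  expect_equal(st$max_fold_variability[i], 1)
  tm <- attr(st, "tissue_mean_log2")
  expect_true(all(tm["const8", ] == 3))

  # tissue log2 means 2 and 6: population SD 2, max deviation 2, 16-fold
  j <- match("spread", st$gene_id)
  expect_equal(st$sd_across_tissues[j], 2)
  expect_equal(st$max_abs_dev[j], 2)
  expect_equal(st$max_fold_variability[j], 16)

  k <- match("haszero", st$gene_id)
  expect_false(st$available[k])
  expect_true(is.na(st$sd_across_tissues[k]))
})

test_that("stability statistics match the brute-force oracle", {
  sim <- generate_dataset(small_sim_config(seed = 9))
  st <- stability_stats(sim$matrix, sim$metadata)
  orc <- oracle_stability(sim$matrix, sim$metadata)
  ok <- st$available
  expect_equal(st$min_sample_fpkm, orc$min_sample_fpkm, tolerance = 1e-12)
  expect_equal(st$sd_across_tissues[ok], orc$sd_across_tissues[ok],
               tolerance = 1e-12)
  expect_equal(st$max_abs_dev[ok], orc$max_abs_dev[ok], tolerance = 1e-12)
  expect_equal(st$max_fold_variability[ok], orc$max_fold_variability[ok],
               tolerance = 1e-12)
})

test_that("housekeeping and reference tiers apply the strict criteria", {
  m <- rbind(hi = rep(100, 4), mid = rep(10, 4), lowdip = c(100, 100, 100, 0.5),
             zero = c(0, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  meta <- four_sample_meta(colnames(m), rep(c("A", "B"), each = 2))
  st <- stability_stats(m, meta)
  cfg <- analysis_config()
  hk <- identify_housekeeping(st, cfg)
  rf <- select_reference_genes(st, cfg)
  expect_setequal(hk$genes, c("hi", "mid"))
  expect_identical(rf$genes, "hi")  # mid fails FPKM > 50
  d <- hk$diagnostics
  expect_match(d$failed[d$gene_id == "lowdip"], "criterion \\(i\\)")
  expect_match(d$failed[d$gene_id == "zero"], "criterion \\(i\\)")
  # boundary genes are excluded under the strict inequalities
  mb <- rbind(atone = rep(1, 4))
  colnames(mb) <- colnames(m)
  stb <- stability_stats(mb, meta)
  expect_length(identify_housekeeping(stb, cfg)$genes, 0)
})

test_that("reference tier is nested in the housekeeping tier", {
  cfg <- analysis_config()
  for (seed in 1:5) {
    sim <- generate_dataset(small_sim_config(seed = seed))
    st <- stability_stats(sim$matrix, sim$metadata)
    hk <- identify_housekeeping(st, cfg)
    rf <- select_reference_genes(st, cfg)
    expect_true(all(rf$genes %in% hk$genes))
  }
})

test_that("relaxing any single criterion never shrinks the selected set", {
  sim <- generate_dataset(small_sim_config(seed = 15))
  st <- stability_stats(sim$matrix, sim$metadata)
  base <- identify_housekeeping(st, analysis_config())$genes
  relaxed <- list(analysis_config(hk_min_fpkm = 0.5),
                  analysis_config(hk_max_sd_log2 = 1.5),
                  analysis_config(hk_max_dev_log2 = 3))
  for (cfg in relaxed) {
    expect_true(all(base %in% identify_housekeeping(st, cfg)$genes))
  }
})

test_that("variability report exposes unstable classic controls", {
  meta <- four_sample_meta(paste0("s", 1:4), rep(c("A", "B"), each = 2))
  m <- rbind(stable = rep(64, 4), gapdh_like = c(1, 1, 41, 41))
  colnames(m) <- paste0("s", 1:4)
  st <- stability_stats(m, meta)
  rep_ <- gene_variability_report(st, c("stable", "gapdh_like"))
  expect_equal(rep_$max_fold_variability[1], 1)
  expect_equal(rep_$max_fold_variability[2], 41, tolerance = 1e-9)
  expect_true(rep_$housekeeping[1])
  expect_false(rep_$housekeeping[2])
  expect_error(gene_variability_report(st, "nope"), "unknown gene")
})

test_that("a planted 64-fold unstable gene is rejected under criterion (iii)", {
  sim <- generate_dataset(small_sim_config(seed = 10))
  m <- sim$matrix
  hk_gene <- sim$truth$gene_id[sim$truth$class == "housekeeping"][1]
  boost <- sim$metadata$sample_id[sim$metadata$tissue == "liver"]
  m[hk_gene, boost] <- m[hk_gene, boost] * 64
  st <- stability_stats(m, sim$metadata)
  rep_ <- gene_variability_report(st, hk_gene)
  expect_gt(rep_$max_fold_variability, 32)
  expect_false(rep_$housekeeping)
  expect_match(rep_$failed_hk, "iii")
})

test_that("homology overlap reports both directional percentages", {
  own <- sprintf("mm%05d", 1:4781)
  foreign <- sprintf("hs%05d", 1:3506)
  # 2,608 foreign genes map into the own list, the rest map elsewhere
  mapping <- data.frame(
    gene_id = c(own[1:2608], sprintf("mmX%04d", 1:898)),
    foreign_id = foreign)
  ov <- homology_overlap(own, foreign, mapping)
  expect_equal(ov$overlap, 2608)
  expect_equal(ov$pct_of_mapped_foreign, 74.4)
  expect_equal(ov$pct_of_own, 54.5)

  disjoint <- homology_overlap(own[1:10],
                               "hsZZ",
                               data.frame(gene_id = "mmZZ", foreign_id = "hsZZ"))
  expect_equal(disjoint$overlap, 0)
  expect_equal(disjoint$pct_of_mapped_foreign, 0)
})

test_that("chromosome distribution conserves counts and fractions", {
  ann <- gene_annotation(data.frame(
    gene_id = paste0("g", 1:10), symbol = "s", biotype = "protein_coding",
    chromosome = c(rep("chr1", 6), rep("chr2", 4))))
  cd <- chromosome_distribution(paste0("g", 1:3), ann)
  expect_equal(sum(cd$count), 3)
  expect_equal(cd$count[cd$chromosome == "chr1"], 3)
  expect_equal(cd$fraction[cd$chromosome == "chr1"], 0.5)
  expect_error(chromosome_distribution("gX", ann), "unannotated")

  sim <- generate_dataset(small_sim_config(seed = 9))
  hk <- sim$truth$gene_id[sim$truth$class == "housekeeping"]
  cd2 <- chromosome_distribution(hk, sim$annotation)
  expect_equal(sum(cd2$count), length(hk))
  # direct division oracle
  for (r in seq_len(nrow(cd2))) {
    expect_equal(cd2$fraction[r],
                 sum(sim$annotation$chromosome[match(hk, sim$annotation$gene_id)] ==
                       cd2$chromosome[r]) /
                   sum(sim$annotation$chromosome == cd2$chromosome[r]),
                 tolerance = 1e-12)
  }
})
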