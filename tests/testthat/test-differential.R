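two_tissue_logm <- function(n_genes = 200, n_per = 4, delta = 0, seed = 21) {
  set.seed(seed)
  a <- matrix(rnorm(n_genes * n_per, 3, 1), n_genes, n_per)
  b <- matrix(rnorm(n_genes * n_per, 3, 1), n_genes, n_per) + delta
  vals <- pmax(cbind(a, b), 0)
  dimnames(vals) <- list(sprintf("g%03d", seq_len(n_genes)),
                         c(paste0("A", seq_len(n_per)), paste0("B", seq_len(n_per))))
  meta <- data.frame(sample_id = colnames(vals),
                     tissue = rep(c("A", "B"), each = n_per),
                     sex = rep(c("female", "male"), n_per),
                     individual = paste0("m", seq_len(2 * n_per)))
  list(logm = structure(list(values = vals, removed_genes = character(0),
                             pseudocount = 1), class = "bm_log_matrix"),
       meta = sample_metadata(meta))
}

test_that("identical groups yield no calls and p = 1 for constants", {
  fx <- two_tissue_logm()
  vals <- fx$logm$values
  vals[, 5:8] <- vals[, 1:4]  # tissue B identical to tissue A gene-wise
  fx$logm$values <- vals
  tab <- pairwise_deg(fx$logm, fx$meta, "A", "B")
  expect_true(all(tab$call == "none"))
  expect_true(all(tab$q_value == 1))

  const <- fx$logm
  const$values[] <- 2
  tab2 <- pairwise_deg(const, fx$meta, "A", "B")
  expect_true(all(tab2$p_value == 1))
})

test_that("Welch p-values match the hand-coded formula oracle", {
  fx <- two_tissue_logm(n_genes = 1000, seed = 21)
  tab <- pairwise_deg(fx$logm, fx$meta, "A", "B")
  a <- fx$logm$values[, 1:4]; b <- fx$logm$values[, 5:8]
  p_oracle <- vapply(seq_len(nrow(a)),
                     function(i) oracle_welch_p(a[i, ], b[i, ]), numeric(1))
  expect_equal(tab$p_value, p_oracle, tolerance = 1e-10)
  # and agree with stats::t.test on a subsample
  for (i in c(1, 57, 500, 999)) {
    expect_equal(tab$p_value[i], stats::t.test(a[i, ], b[i, ])$p.value,
                 tolerance = 1e-10)
  }
  pooled <- row_t_test(a, b, var_equal = TRUE)
  for (i in c(2, 101)) {
    expect_equal(pooled$p_value[i],
                 stats::t.test(a[i, ], b[i, ], var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("BH q-values equal the brute-force step-up exactly", {
  set.seed(7)
  for (rep in 1:5) {
    p <- runif(200)^(rep / 2)
    expect_identical(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
  p <- c(0.01, 0.01, 0.5, 1)  # ties and the cap
  expect_identical(bh_adjust(p), oracle_bh(p))
  expect_true(all(bh_adjust(p) >= p & bh_adjust(p) <= 1))
  expect_length(bh_adjust(numeric(0)), 0)
})

test_that("DEG count matrix is antisymmetric and recovers planted effects", {
  fx <- two_tissue_logm(n_genes = 300, seed = 33)
  # plant 50 genes up in A at 8-fold (3 log2 units), low noise
  set.seed(33)
  vals <- fx$logm$values
  vals[1:50, 1:4] <- matrix(rnorm(200, 6, 0.2), 50, 4)
  vals[1:50, 5:8] <- matrix(rnorm(200, 3, 0.2), 50, 4)
  fx$logm$values <- vals
  dc <- deg_count_matrix(fx$logm, fx$meta)
  expect_equal(dc$up["A", "B"], dc$down["B", "A"])
  expect_equal(dc$down["A", "B"], dc$up["B", "A"])
  expect_true(dc$up["A", "B"] >= 45 && dc$up["A", "B"] <= 50)

  const <- fx$logm
  const$values[] <- rep(runif(nrow(vals), 1, 4), ncol(vals))
  expect_true(all(deg_count_matrix(const, fx$meta)$up == 0))
})

test_that("DEG counts are antisymmetric across a 17-tissue simulation", {
  sim <- generate_dataset(small_sim_config(seed = 31, n_genes = 300L))
  logm <- make_log_matrix(sim$matrix)
  dc <- deg_count_matrix(logm, sim$metadata)
  expect_identical(dc$up, t(dc$down))
  expect_true(all(diag(dc$up) == 0))
})

test_that("tissue-specific calls follow the fold definition and nest", {
  m <- rbind(spec = c(100, 100, 1, 0.5, 0.2, 0.1),
             flat = c(5, 5, 5, 5, 5, 5),
             low = c(0.05, 0.05, 0.001, 0.001, 0.001, 0.001))
  colnames(m) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = colnames(m),
                     tissue = rep(c("A", "B", "C"), each = 2),
                     sex = "female", individual = "m1")
  ts <- tissue_specific(m, meta, fc_grid = c(2, 4, 8, 16, 32))
  # min over other tissues: (100 + pc) / (max(other means) + pc)
  expect_equal(ts$table$achieved_fc[1], (100 + 0.01) / (0.75 + 0.01))
  for (f in c("2", "4", "8", "16", "32")) {
    expect_true("spec" %in% ts$calls[[f]]$gene_id)
    expect_false("flat" %in% ts$calls[[f]]$gene_id)
    expect_false("low" %in% ts$calls[[f]]$gene_id)  # below expressed threshold
  }
  expect_equal(ts$calls[["2"]]$specific_tissue[ts$calls[["2"]]$gene_id == "spec"], "A")

  sim <- generate_dataset(small_sim_config(seed = 17))
  tss <- tissue_specific(sim$matrix, sim$metadata)
  sets <- lapply(tss$calls, function(d) d$gene_id)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  # brute-force recomputation at the 4-fold threshold
  tm <- sapply(unique(sim$metadata$tissue), function(t) {
    rowMeans(sim$matrix[, sim$metadata$sample_id[sim$metadata$tissue == t],
                        drop = FALSE])
  })
  brute <- rownames(tm)[vapply(seq_len(nrow(tm)), function(i) {
    x <- tm[i, ]; b <- which.max(x)
    all((x[b] + 0.01) / (x[-b] + 0.01) > 4) && x[b] >= 0.1
  }, logical(1))]
  expect_setequal(sets[["4"]], brute)
})

test_that("sex-dominated calling is fold-based and tissue-guarded", {
  m <- rbind(fem = c(10, 10, 4, 4), none = c(5, 5, 5, 5), mal = c(1, 1, 9, 9))
  colnames(m) <- paste0("s", 1:4)
  meta <- sample_metadata(data.frame(
    sample_id = colnames(m), tissue = "heart",
    sex = c("female", "female", "male", "male"),
    individual = paste0("m", 1:4), sexual_tissue = FALSE))
  res <- sex_dominated(m, meta, "heart", fc = 2)
  expect_identical(res$female_dominated, "fem")  # fold 10.01/4.01 = 2.496 > 2
  expect_identical(res$male_dominated, "mal")
  expect_length(intersect(res$female_dominated, res$male_dominated), 0)
  expect_equal(res$table$log2_fold_f_over_m[1], log2(10.01 / 4.01))

  meta_sex <- meta
  meta_sex$tissue <- "ovary"
  meta_sex$sex <- "female"
  meta_sex$sexual_tissue <- TRUE
  expect_error(sex_dominated(m, sample_metadata(meta_sex), "ovary"),
               "sexual tissue")
})

test_that("planted sex-dominated genes are recovered", {
  sim <- generate_dataset(small_sim_config(seed = 29, n_sex_dominated = 4L))
  truth <- sim$truth[sim$truth$class == "sex_dominated", ]
  res <- sex_dominated_all(sim$matrix, sim$metadata, fc = 2)
  hit <- mapply(function(g, t, s) {
    r <- res[[t]]
    g %in% (if (s == "female") r$female_dominated else r$male_dominated)
  }, truth$gene_id, truth$target_tissue, truth$target_sex)
  expect_gte(mean(hit), 0.9)
  for (r in res) {
    expect_length(intersect(r$female_dominated, r$male_dominated), 0)
  }
  expect_false(any(c("ovary", "testis", "uterus", "vesicular_gland") %in%
                   names(res)))
})
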