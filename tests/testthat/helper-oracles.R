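# Independent brute-force oracles and tiny fixture builders. The oracles are
# deliberately written from first principles (textbook formulas, explicit
# loops) and never call the package's own code paths.

# Welch two-sample t-test from the textbook formula, one gene at a time.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(t), df)
}

# Benjamini-Hochberg step-up: sort ascending, p * m / i, running minimum
# from the top, original order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Pairwise 1 - Pearson distance via explicit sums.
oracle_pearson_dist <- function(vals) {
  n <- ncol(vals)
  d <- matrix(0, n, n, dimnames = list(colnames(vals), colnames(vals)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- vals[, i]; y <- vals[, j]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      d[i, j] <- 1 - r
    }
  }
  diag(d) <- 0
  d
}

# Stability statistics recomputed gene by gene with explicit loops.
oracle_stability <- function(mat, meta) {
  tissues <- unique(meta$tissue)
  out <- data.frame(gene_id = rownames(mat), min_sample_fpkm = NA_real_,
                    sd_across_tissues = NA_real_, max_abs_dev = NA_real_,
                    max_fold_variability = NA_real_)
  for (g in seq_len(nrow(mat))) {
    x <- mat[g, ]
    out$min_sample_fpkm[g] <- min(x)
    if (min(x) <= 0) next
    tmeans <- sapply(tissues, function(t) {
      mean(log2(x[meta$sample_id[meta$tissue == t]]))
    })
    ctr <- mean(tmeans)
    out$sd_across_tissues[g] <- sqrt(mean((tmeans - ctr)^2))
    out$max_abs_dev[g] <- max(abs(tmeans - ctr))
    out$max_fold_variability[g] <- 2^(max(tmeans) - min(tmeans))
  }
  out
}

# R^2 of a simple regression via stats::lm on a data.frame.
oracle_r2 <- function(x, y) {
  summary(stats::lm(y ~ x, data = data.frame(x = x, y = y)))$r.squared
}

# --- fixtures ---------------------------------------------------------------

# Tiny hand-built triple: n_genes x n_samples constant-free matrix with two
# tissues and both sexes.
tiny_triple <- function(n_genes = 10L, n_samples = 4L) {
  set.seed(99)
  m <- matrix(round(runif(n_genes * n_samples, 0, 20), 3),
              n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%d", seq_len(n_samples))))
  ann <- data.frame(gene_id = rownames(m),
                    symbol = paste0("sym", seq_len(n_genes)),
                    biotype = rep(c("protein_coding", "lncRNA",
                                    "processed_pseudogene", "TEC"),
                                  length.out = n_genes),
                    chromosome = rep(c("chr1", "chr2"), length.out = n_genes))
  meta <- data.frame(sample_id = colnames(m),
                     tissue = rep(c("liver", "brain"), each = n_samples / 2),
                     sex = rep(c("female", "male"), n_samples / 2),
                     individual = paste0("m", seq_len(n_samples)))
  list(matrix = m, annotation = ann, metadata = meta)
}

# Small fast simulation for unit tests; planted counts scale with n_genes
# and any simulation_config argument can be overridden.
small_sim_config <- function(seed = 1L, n_genes = 600L, ...) {
  args <- list(n_genes = n_genes,
               n_housekeeping = max(10L, as.integer(n_genes * 0.10)),
               n_reference = max(2L, as.integer(n_genes * 0.017)),
               n_tissue_specific = max(1L, as.integer(n_genes * 0.008)),
               n_sex_dominated = max(1L, as.integer(n_genes * 0.003)),
               seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulation_config, args)
}
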