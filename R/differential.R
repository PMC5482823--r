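# Pairwise tissue differential expression (Welch t + BH), tissue-specific
# calling across a fold-change grid, and sex-dominated calling.

#' Row-wise Welch (or pooled) two-sample t-test
#'
#' Vectorised over genes. With unequal variances (default) the
#' Welch-Satterthwaite degrees of freedom are used. Genes with zero variance
#' in both groups get p = 1 when the means are equal and p = 0 otherwise.
#'
#' @param a,b Numeric matrices (genes x samples), same rownames.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return data.frame: `mean_a`, `mean_b`, `t`, `df`, `p_value`.
#' @export
row_t_test <- function(a, b, var_equal = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stopf("each group needs >= 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (ifelse(va > 0, (va / na)^2 / (na - 1L), 0) +
       ifelse(vb > 0, (vb / nb)^2 / (nb - 1L), 0))
  }
  tstat <- (ma - mb) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    equal <- degenerate & (ma == mb)
    tstat[degenerate] <- ifelse(equal[degenerate], 0, Inf * sign(ma - mb)[degenerate])
    df[degenerate] <- NA_real_
    p[degenerate] <- ifelse(equal[degenerate], 1, 0)
  }
  data.frame(mean_a = ma, mean_b = mb, t = tstat, df = df, p_value = p,
             row.names = rownames(a))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up: sort p ascending, multiply by m/i, enforce monotonicity
#' with a running minimum from the largest p, cap at 1. Matches
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

tissue_columns <- function(meta, tissue) {
  cols <- meta$sample_id[meta$tissue == tissue]
  if (!length(cols)) stopf("unknown tissue '%s'", tissue)
  cols
}

#' Differentially expressed genes between two tissues
#'
#' Two-sided t-test per gene on the log2 values (Welch by default), BH
#' adjustment over all genes tested for this pair, and a fold filter on
#' linear-scale tissue means with a small pseudocount. A gene is called when
#' `q < alpha` and the linear fold change is `>= fc` or `<= 1/fc`.
#'
#' @param logm A `bm_log_matrix`.
#' @param meta Sample metadata.
#' @param tissue_a,tissue_b Tissue labels; each needs >= 2 samples.
#' @param alpha BH FDR level.
#' @param fc Minimum linear fold change.
#' @param fc_pseudocount Pseudocount for the fold ratio.
#' @param var_equal Pooled-variance test instead of Welch.
#' @return data.frame of class `bm_deg_table`: `gene_id`, `mean_a`, `mean_b`
#'   (linear FPKM), `log2fc`, `p_value`, `q_value`,
#'   `call` in `up_in_a` / `down_in_a` / `none`.
#' @export
pairwise_deg <- function(logm, meta, tissue_a, tissue_b, alpha = 0.05, fc = 2,
                         fc_pseudocount = 0.01, var_equal = FALSE) {
  vals <- logm$values
  ca <- tissue_columns(meta, tissue_a)
  cb <- tissue_columns(meta, tissue_b)
  if (length(ca) < 2L || length(cb) < 2L) {
    stopf("pairwise DEG needs >= 2 samples per tissue ('%s': %d, '%s': %d)",
          tissue_a, length(ca), tissue_b, length(cb))
  }
  tt <- row_t_test(vals[, ca, drop = FALSE], vals[, cb, drop = FALSE],
                   var_equal = var_equal)
  # linear-scale means recovered from the log matrix
  lin_a <- rowMeans(2^vals[, ca, drop = FALSE] - logm$pseudocount)
  lin_b <- rowMeans(2^vals[, cb, drop = FALSE] - logm$pseudocount)
  log2fc <- log2((lin_a + fc_pseudocount) / (lin_b + fc_pseudocount))
  q <- bh_adjust(tt$p_value)
  call <- rep("none", nrow(vals))
  hit <- q < alpha & abs(log2fc) >= log2(fc)
  call[hit & log2fc > 0] <- "up_in_a"
  call[hit & log2fc < 0] <- "down_in_a"
  structure(data.frame(gene_id = rownames(vals),
                       mean_a = lin_a, mean_b = lin_b, log2fc = log2fc,
                       p_value = tt$p_value, q_value = q, call = call,
                       stringsAsFactors = FALSE),
            class = c("bm_deg_table", "data.frame"),
            tissue_a = tissue_a, tissue_b = tissue_b, alpha = alpha, fc = fc)
}

#' Up/down DEG counts for every tissue pair
#'
#' Entry `up[A, B]` is the number of genes up in tissue A versus tissue B;
#' `down[A, B]` the number down. By construction `up[A, B] == down[B, A]`.
#'
#' @inheritParams pairwise_deg
#' @return list of class `bm_deg_counts` with matrices `up` and `down`.
#' @export
deg_count_matrix <- function(logm, meta, alpha = 0.05, fc = 2,
                             fc_pseudocount = 0.01, var_equal = FALSE) {
  tissues <- unique(meta$tissue)
  if (length(tissues) < 2L) stopf("need >= 2 tissues")
  up <- matrix(0L, length(tissues), length(tissues),
               dimnames = list(tissues, tissues))
  down <- up
  for (i in seq_along(tissues)) {
    for (j in seq_along(tissues)) {
      if (j <= i) next
      tab <- pairwise_deg(logm, meta, tissues[i], tissues[j], alpha, fc,
                          fc_pseudocount, var_equal)
      up[i, j] <- sum(tab$call == "up_in_a")
      down[i, j] <- sum(tab$call == "down_in_a")
      up[j, i] <- down[i, j]
      down[j, i] <- up[i, j]
    }
  }
  structure(list(up = up, down = down), class = "bm_deg_counts")
}

#' Tissue-specific gene calling over a fold-change grid
#'
#' For each gene, the candidate tissue is the one with the highest linear
#' mean; the achieved fold is the minimum over all other tissues of
#' `(mean_candidate + pc) / (mean_other + pc)`. The gene is specific to the
#' candidate at threshold `f` when the achieved fold exceeds `f` and the
#' candidate mean is itself at or above the expressed threshold (no
#' "specific" calls among near-silent genes). Calls are nested along the
#' grid: every call at a higher threshold is a call at every lower one.
#'
#' @param matrix FPKM matrix (linear scale).
#' @param meta Sample metadata.
#' @param fc_grid Fold thresholds.
#' @param fc_pseudocount Pseudocount for the ratios.
#' @param min_mean Minimum candidate-tissue mean FPKM.
#' @return list of class `bm_ts_calls`: `table` (`gene_id`,
#'   `candidate_tissue`, `achieved_fc`, `candidate_mean`), `calls` (named
#'   list over thresholds; data.frame `gene_id`, `specific_tissue`),
#'   `fc_grid`.
#' @export
tissue_specific <- function(matrix, meta, fc_grid = c(2, 4, 8, 16, 32),
                            fc_pseudocount = 0.01, min_mean = 0.1) {
  tissues <- unique(meta$tissue)
  if (length(tissues) < 2L) stopf("need >= 2 tissues")
  tm <- vapply(tissues, function(t) {
    rowMeans(matrix[, tissue_columns(meta, t), drop = FALSE])
  }, numeric(nrow(matrix)))
  if (is.null(dim(tm))) {
    tm <- base::matrix(tm, nrow = 1L, dimnames = list(rownames(matrix), tissues))
  }
  best <- max.col(tm, ties.method = "first")
  best_mean <- tm[cbind(seq_len(nrow(tm)), best)]
  second <- apply(tm, 1L, function(x) max(x[-which.max(x)]))
  achieved <- (best_mean + fc_pseudocount) / (second + fc_pseudocount)
  tab <- data.frame(gene_id = rownames(matrix),
                    candidate_tissue = tissues[best],
                    achieved_fc = achieved,
                    candidate_mean = best_mean,
                    stringsAsFactors = FALSE)
  fc_grid <- sort(fc_grid)
  calls <- lapply(fc_grid, function(f) {
    sel <- achieved > f & best_mean >= min_mean
    data.frame(gene_id = tab$gene_id[sel],
               specific_tissue = tab$candidate_tissue[sel],
               stringsAsFactors = FALSE)
  })
  names(calls) <- as.character(fc_grid)
  structure(list(table = tab, calls = calls, fc_grid = fc_grid),
            class = "bm_ts_calls")
}

#' Sex-dominated genes within one non-sexual tissue
#'
#' A gene is female-dominated in a tissue when
#' `(mean_female + pc) / (mean_male + pc) > fc` over that tissue's samples;
#' male-dominated symmetrically. Fold-only by default, matching designs with
#' very few replicates per sex; `test = TRUE` additionally requires a Welch
#' q-value below `alpha` (needs >= 2 samples per sex).
#'
#' @param matrix FPKM matrix.
#' @param meta Sample metadata.
#' @param tissue A non-sexual tissue label.
#' @param fc Fold cutoff.
#' @param fc_pseudocount Pseudocount for the ratio.
#' @param test Also require a BH-adjusted Welch test on log2(FPKM+1).
#' @param alpha FDR level when `test = TRUE`.
#' @return list of class `bm_sex_calls`: `tissue`, `female_dominated`,
#'   `male_dominated` (gene id vectors, disjoint) and `table` with per-gene
#'   means and achieved log2 fold (female over male).
#' @export
sex_dominated <- function(matrix, meta, tissue, fc = 2, fc_pseudocount = 0.01,
                          test = FALSE, alpha = 0.05) {
  sub <- meta[meta$tissue == tissue, , drop = FALSE]
  if (!nrow(sub)) stopf("unknown tissue '%s'", tissue)
  if (any(sub$sexual_tissue)) {
    stopf("'%s' is a sexual tissue; sex-dominated calling applies to non-sexual tissues",
          tissue)
  }
  cf <- sub$sample_id[sub$sex == "female"]
  cm <- sub$sample_id[sub$sex == "male"]
  if (!length(cf) || !length(cm)) {
    stopf("tissue '%s' needs >= 1 sample per sex", tissue)
  }
  mf <- rowMeans(matrix[, cf, drop = FALSE])
  mm <- rowMeans(matrix[, cm, drop = FALSE])
  fold_f_over_m <- (mf + fc_pseudocount) / (mm + fc_pseudocount)
  fem <- fold_f_over_m > fc
  mal <- 1 / fold_f_over_m > fc
  if (test) {
    lg <- log2(matrix + 1)
    tt <- row_t_test(lg[, cf, drop = FALSE], lg[, cm, drop = FALSE])
    q <- bh_adjust(tt$p_value)
    fem <- fem & q < alpha
    mal <- mal & q < alpha
  }
  structure(list(tissue = tissue,
                 female_dominated = rownames(matrix)[fem],
                 male_dominated = rownames(matrix)[mal],
                 table = data.frame(gene_id = rownames(matrix),
                                    mean_female = mf, mean_male = mm,
                                    log2_fold_f_over_m = log2(fold_f_over_m),
                                    stringsAsFactors = FALSE)),
            class = "bm_sex_calls")
}

#' Sex-dominated genes across every non-sexual tissue
#'
#' @inheritParams sex_dominated
#' @return Named list of [sex_dominated()] results, one per non-sexual tissue.
#' @export
sex_dominated_all <- function(matrix, meta, fc = 2, fc_pseudocount = 0.01,
                              test = FALSE, alpha = 0.05) {
  tissues <- unique(meta$tissue[!meta$sexual_tissue])
  res <- lapply(tissues, function(t) {
    sex_dominated(matrix, meta, t, fc, fc_pseudocount, test, alpha)
  })
  names(res) <- tissues
  res
}
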