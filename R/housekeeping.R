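# Two-tier housekeeping / reference gene selection by expression stability,
# variability diagnostics, homology overlap and chromosome distribution.

#' Per-gene expression stability statistics across tissues
#'
#' For every gene with strictly positive FPKM in all samples: the per-tissue
#' mean of `log2(FPKM)` (no pseudocount — candidates are guaranteed above
#' 1 FPKM by the selection criteria, and genes containing a zero auto-fail
#' instead of being rescued), the SD of those tissue means (population SD by
#' default: the tissue panel is the whole frame of reference), the maximum
#' absolute deviation of any tissue mean from the cross-tissue average, and
#' the maximal fold variability `2^(max - min tissue mean)`. Genes with any
#' zero get `NA` statistics and `available = FALSE`.
#'
#' @param matrix FPKM matrix.
#' @param meta Sample metadata (every tissue needs >= 1 sample).
#' @param per_sample Compute spread over individual samples instead of
#'   per-tissue means.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return data.frame of class `bm_stability`: `gene_id`, `min_sample_fpkm`,
#'   `sd_across_tissues`, `max_abs_dev`, `max_fold_variability`, `available`;
#'   attribute `tissue_mean_log2` holds the gene x tissue mean matrix.
#' @export
stability_stats <- function(matrix, meta, per_sample = FALSE,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  tissues <- unique(meta$tissue)
  min_fpkm <- apply(matrix, 1L, min)
  ok <- min_fpkm > 0
  lg <- matrix * NA_real_
  lg[ok, ] <- log2(matrix[ok, , drop = FALSE])

  units <- if (per_sample) {
    lg
  } else {
    tm <- vapply(tissues, function(t) {
      rowMeans(lg[, tissue_columns(meta, t), drop = FALSE])
    }, numeric(nrow(matrix)))
    if (is.null(dim(tm))) {
      tm <- base::matrix(tm, nrow = 1L, dimnames = list(rownames(matrix), tissues))
    }
    tm
  }
  ctr <- rowMeans(units)
  n <- ncol(units)
  ss <- rowSums((units - ctr)^2)
  sdv <- sqrt(ss / if (sd_type == "population") n else n - 1L)
  max_dev <- apply(abs(units - ctr), 1L, max)
  fold_var <- 2^(apply(units, 1L, max) - apply(units, 1L, min))

  out <- data.frame(gene_id = rownames(matrix),
                    min_sample_fpkm = min_fpkm,
                    sd_across_tissues = ifelse(ok, sdv, NA_real_),
                    max_abs_dev = ifelse(ok, max_dev, NA_real_),
                    max_fold_variability = ifelse(ok, fold_var, NA_real_),
                    available = ok, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("bm_stability", "data.frame"),
            tissue_mean_log2 = if (!per_sample) units else NULL,
            sd_type = sd_type, per_sample = per_sample)
}

select_stable <- function(stats, min_fpkm, max_sd, max_dev) {
  pass_i <- stats$available & stats$min_sample_fpkm > min_fpkm
  pass_ii <- stats$available & stats$sd_across_tissues < max_sd
  pass_iii <- stats$available & stats$max_abs_dev < max_dev
  selected <- pass_i & pass_ii & pass_iii
  labels <- c("(i) not highly expressed in all samples",
              "(ii) cross-tissue SD too high",
              "(iii) exceptional tissue expression")
  pass <- cbind(i = pass_i, ii = pass_ii, iii = pass_iii)
  failed <- apply(pass, 1L, function(p) {
    if (all(p)) NA_character_
    else paste("criterion", paste(labels[!p], collapse = "; criterion "))
  })
  list(selected = selected, failed = unname(failed), pass = pass)
}

#' Identify housekeeping genes
#'
#' A gene is a housekeeping candidate when (i) it is highly expressed in all
#' samples (`min FPKM > hk_min_fpkm`, strict), (ii) its cross-tissue SD of
#' log2 expression is below `hk_max_sd_log2`, and (iii) no tissue mean
#' deviates from the cross-tissue average by `hk_max_dev_log2` or more log2
#' units (i.e. no four-fold exceptional tissue at the default of 2).
#'
#' @param stats Output of [stability_stats()].
#' @param config An [analysis_config()].
#' @return list of class `bm_hk_result`: `genes` (selected ids), `tier`,
#'   `diagnostics` (per-gene stats, per-criterion pass flags, and the failed
#'   criteria for rejected genes).
#' @export
identify_housekeeping <- function(stats, config = analysis_config()) {
  sel <- select_stable(stats, config$hk_min_fpkm, config$hk_max_sd_log2,
                       config$hk_max_dev_log2)
  diag <- cbind(stats, selected = sel$selected,
                pass_i = sel$pass[, "i"], pass_ii = sel$pass[, "ii"],
                pass_iii = sel$pass[, "iii"],
                failed = sel$failed)
  structure(list(genes = stats$gene_id[sel$selected], tier = "housekeeping",
                 diagnostics = diag),
            class = "bm_hk_result")
}

#' Select the reference-gene tier
#'
#' Housekeeping criteria tightened for normalization controls: FPKM above
#' `ref_min_fpkm` in every sample, cross-tissue SD below `ref_max_sd_log2`,
#' and no tissue deviating by `ref_max_dev_log2` (two-fold) or more. With the
#' default thresholds the reference set is a subset of the housekeeping set.
#'
#' @inheritParams identify_housekeeping
#' @return list of class `bm_hk_result` with `tier = "reference"`.
#' @export
select_reference_genes <- function(stats, config = analysis_config()) {
  sel <- select_stable(stats, config$ref_min_fpkm, config$ref_max_sd_log2,
                       config$ref_max_dev_log2)
  diag <- cbind(stats, selected = sel$selected,
                pass_i = sel$pass[, "i"], pass_ii = sel$pass[, "ii"],
                pass_iii = sel$pass[, "iii"],
                failed = sel$failed)
  structure(list(genes = stats$gene_id[sel$selected], tier = "reference",
                 diagnostics = diag),
            class = "bm_hk_result")
}

#' Maximal fold-variability report for chosen genes
#'
#' The classic "is Gapdh actually stable?" diagnostic: for each requested
#' gene, its maximal cross-tissue fold variability and whether it passes the
#' housekeeping and reference tiers, with the failed criteria spelled out.
#'
#' @param stats Output of [stability_stats()].
#' @param gene_ids Genes to report (ids or symbols resolved upstream).
#' @param config An [analysis_config()].
#' @return data.frame: `gene_id`, `max_fold_variability`, `housekeeping`,
#'   `reference`, `failed_hk`.
#' @export
gene_variability_report <- function(stats, gene_ids,
                                    config = analysis_config()) {
  idx <- match(gene_ids, stats$gene_id)
  if (anyNA(idx)) stopf("unknown gene id(s): %s", fmt_ids(gene_ids[is.na(idx)]))
  hk <- select_stable(stats, config$hk_min_fpkm, config$hk_max_sd_log2,
                      config$hk_max_dev_log2)
  rf <- select_stable(stats, config$ref_min_fpkm, config$ref_max_sd_log2,
                      config$ref_max_dev_log2)
  data.frame(gene_id = gene_ids,
             max_fold_variability = stats$max_fold_variability[idx],
             housekeeping = hk$selected[idx],
             reference = rf$selected[idx],
             failed_hk = hk$failed[idx],
             stringsAsFactors = FALSE)
}

#' Overlap between a gene set and a foreign (other-species) set
#'
#' Maps the foreign set through a homology table and reports the overlap
#' count and percentages in both directions, rounded to one decimal:
#' `100 * overlap / |mapped foreign set|` and `100 * overlap / |own set|`.
#'
#' @param set_a Own gene ids.
#' @param set_b Foreign gene ids.
#' @param mapping data.frame(`gene_id`, `foreign_id`), one row per homolog
#'   pair.
#' @return list: `overlap`, `n_mapped_foreign`, `n_own`,
#'   `pct_of_mapped_foreign`, `pct_of_own`, `overlap_genes`.
#' @export
homology_overlap <- function(set_a, set_b, mapping) {
  stopifnot(all(c("gene_id", "foreign_id") %in% names(mapping)))
  mapped <- mapping[mapping$foreign_id %in% set_b, , drop = FALSE]
  overlap_genes <- intersect(unique(mapped$gene_id), set_a)
  n_mapped <- length(unique(mapped$foreign_id))
  n_own <- length(unique(set_a))
  list(overlap = length(overlap_genes),
       n_mapped_foreign = n_mapped,
       n_own = n_own,
       pct_of_mapped_foreign = if (n_mapped) round1(100 * length(overlap_genes) / n_mapped) else 0,
       pct_of_own = if (n_own) round1(100 * length(overlap_genes) / n_own) else 0,
       overlap_genes = overlap_genes)
}

#' Chromosome distribution of a gene set
#'
#' Absolute counts per chromosome (summing to the set size) and the count
#' normalized by the total number of annotated genes on that chromosome.
#'
#' @param gene_set Gene ids.
#' @param annotation Validated annotation covering the set.
#' @return data.frame: `chromosome`, `count`, `total_genes`, `fraction`.
#' @export
chromosome_distribution <- function(gene_set, annotation) {
  idx <- match(gene_set, annotation$gene_id)
  if (anyNA(idx)) stopf("unannotated gene(s): %s", fmt_ids(gene_set[is.na(idx)]))
  chroms <- unique(annotation$chromosome)
  cnt <- table(factor(annotation$chromosome[idx], levels = chroms))
  tot <- table(factor(annotation$chromosome, levels = chroms))
  out <- data.frame(chromosome = chroms,
                    count = as.integer(cnt),
                    total_genes = as.integer(tot),
                    stringsAsFactors = FALSE)
  out$fraction <- out$count / out$total_genes
  stopifnot(sum(out$count) == length(gene_set))
  out
}
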