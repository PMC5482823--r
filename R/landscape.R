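# Expression landscape: expressed/ubiquitous flags, biotype and per-tissue
# summaries, log transformation, sample clustering and outlier flagging.

#' Flag expressed and ubiquitously expressed genes
#'
#' A gene is expressed in a sample when its FPKM is at or above `threshold`
#' (the `>=` convention, applied consistently); expressed overall when that
#' holds in at least one sample; ubiquitous when it holds in every sample.
#'
#' @param matrix FPKM matrix.
#' @param threshold Expression threshold in FPKM.
#' @return data.frame of class `bm_flags`: `gene_id`, `n_samples_expressed`,
#'   `expressed`, `ubiquitous`.
#' @export
flag_expressed <- function(matrix, threshold = 0.1) {
  stopifnot(threshold > 0)
  n <- rowSums(matrix >= threshold)
  structure(data.frame(gene_id = rownames(matrix),
                       n_samples_expressed = as.integer(n),
                       expressed = n >= 1L,
                       ubiquitous = n == ncol(matrix),
                       stringsAsFactors = FALSE),
            class = c("bm_flags", "data.frame"),
            threshold = threshold, n_samples = ncol(matrix))
}

#' Expressed/silent counts and percentages per biotype group
#'
#' @param flags Output of [flag_expressed()].
#' @param annotation Validated annotation covering every flagged gene.
#' @return data.frame per biotype group: `total`, `expressed`,
#'   `not_expressed`, `pct_expressed` (one decimal).
#' @export
biotype_summary <- function(flags, annotation) {
  if (is.null(annotation$biotype_group)) annotation <- gene_annotation(annotation)
  idx <- match(flags$gene_id, annotation$gene_id)
  if (anyNA(idx)) {
    stopf("unannotated gene(s): %s", fmt_ids(flags$gene_id[is.na(idx)]))
  }
  grp <- annotation$biotype_group[idx]
  groups <- intersect(BIOTYPE_GROUPS, unique(grp))
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- grp == g
    data.frame(biotype_group = g,
               total = sum(sel),
               expressed = sum(flags$expressed[sel]),
               not_expressed = sum(sel) - sum(flags$expressed[sel]),
               stringsAsFactors = FALSE)
  }))
  out$pct_expressed <- round1(100 * out$expressed / out$total)
  out
}

#' Mean number of expressed genes per tissue
#'
#' Counts genes at or above `threshold` per sample, then summarises within
#' each tissue: the mean of per-sample counts by default, or the size of the
#' union of genes expressed in any sample of the tissue.
#'
#' @param matrix FPKM matrix.
#' @param meta Sample metadata.
#' @param threshold Expression threshold in FPKM.
#' @param mode `"average"` (default) or `"union"`.
#' @return data.frame: `tissue`, `n_samples`, `expressed_genes`.
#' @export
expressed_per_tissue <- function(matrix, meta, threshold = 0.1,
                                 mode = c("average", "union")) {
  mode <- match.arg(mode)
  tissues <- unique(meta$tissue)
  counts <- vapply(tissues, function(t) {
    cols <- meta$sample_id[meta$tissue == t]
    if (!length(cols)) stopf("tissue '%s' has zero samples", t)
    sub <- matrix[, cols, drop = FALSE]
    if (mode == "average") mean(colSums(sub >= threshold))
    else sum(rowSums(sub >= threshold) >= 1L)
  }, numeric(1L))
  data.frame(tissue = tissues,
             n_samples = as.integer(table(meta$tissue)[tissues]),
             expressed_genes = counts, stringsAsFactors = FALSE)
}

#' Remove all-zero rows and log2-transform
#'
#' Genes whose FPKM is zero in every sample are removed (and listed); the
#' remaining values become `log2(FPKM + pseudocount)`.
#'
#' @param matrix FPKM matrix.
#' @param pseudocount Added before the log; 1 by default, so values stay
#'   non-negative.
#' @return list of class `bm_log_matrix`: `values` (log2 matrix),
#'   `removed_genes`, `pseudocount`.
#' @export
make_log_matrix <- function(matrix, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  zero <- rowSums(matrix != 0) == 0L
  structure(list(values = log2(matrix[!zero, , drop = FALSE] + pseudocount),
                 removed_genes = rownames(matrix)[zero],
                 pseudocount = pseudocount),
            class = "bm_log_matrix")
}

#' Hierarchically cluster samples on a correlation distance
#'
#' Pairwise sample distance is `1 - Pearson correlation` over genes of the
#' log2 matrix by default (Spearman and Euclidean available), agglomerated
#' with average linkage (complete and Ward available). The exact metric and
#' linkage of published dendrograms are rarely stated, so both are
#' configurable.
#'
#' @param logm A `bm_log_matrix` (or a plain numeric matrix of log values).
#' @param method Distance: `"pearson"`, `"spearman"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward.D2"`.
#' @return list of class `bm_cluster_report`: `distance` (symmetric matrix,
#'   zero diagonal), `hclust` (merge tree), `method`, `linkage`.
#' @export
cluster_samples <- function(logm, method = c("pearson", "spearman", "euclidean"),
                            linkage = c("average", "complete", "ward.D2")) {
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  vals <- if (inherits(logm, "bm_log_matrix")) logm$values else logm
  if (ncol(vals) < 3L) stopf("clustering needs at least 3 samples")
  if (method %in% c("pearson", "spearman")) {
    sds <- apply(vals, 2L, sd)
    if (any(sds == 0)) {
      stopf("zero-variance sample(s), correlation undefined: %s",
            fmt_ids(colnames(vals)[sds == 0]))
    }
    d <- 1 - cor(vals, method = method)
  } else {
    d <- as.matrix(stats::dist(t(vals)))
  }
  d[abs(d) < .Machine$double.eps^0.75] <- 0
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = linkage)
  structure(list(distance = d, hclust = hc, method = method, linkage = linkage),
            class = "bm_cluster_report")
}

#' Flag samples whose nearest neighbour is from another tissue
#'
#' Operationalises the "one sample does not cluster with its tissue mates"
#' dendrogram check: a sample is flagged when the closest other sample (by
#' the clustering distance) belongs to a different tissue, provided the
#' sample's own tissue has at least two samples (singleton tissues are never
#' flagged).
#'
#' @param report Output of [cluster_samples()].
#' @param meta Sample metadata.
#' @return data.frame: `sample_id`, `tissue`, `nearest_neighbor`,
#'   `neighbor_tissue`, `flagged`, `reason`.
#' @export
flag_outliers <- function(report, meta) {
  d <- report$distance
  ids <- colnames(d)
  tis <- meta$tissue[match(ids, meta$sample_id)]
  if (anyNA(tis)) stopf("sample(s) missing metadata: %s", fmt_ids(ids[is.na(tis)]))
  tissue_sizes <- table(tis)
  out <- data.frame(sample_id = ids, tissue = tis,
                    nearest_neighbor = NA_character_,
                    neighbor_tissue = NA_character_,
                    flagged = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    dd <- d[i, -i]
    nn <- names(dd)[which.min(dd)]
    out$nearest_neighbor[i] <- nn
    out$neighbor_tissue[i] <- tis[match(nn, ids)]
    eligible <- tissue_sizes[[tis[i]]] >= 2L
    if (eligible && out$neighbor_tissue[i] != tis[i]) {
      out$flagged[i] <- TRUE
      out$reason[i] <- sprintf(
        "nearest neighbor '%s' is from tissue '%s', not '%s'",
        nn, out$neighbor_tissue[i], tis[i])
    }
  }
  out
}

#' Thin PCA summary of a log matrix
#'
#' Component scores and explained-variance fractions from [stats::prcomp()];
#' a convenience view with no logic of its own.
#'
#' @param logm A `bm_log_matrix` or numeric matrix.
#' @param n_components Number of components to keep.
#' @return list with `scores` (samples x components) and
#'   `explained_variance` (fractions).
#' @export
pca_summary <- function(logm, n_components = 2L) {
  vals <- if (inherits(logm, "bm_log_matrix")) logm$values else logm
  p <- prcomp(t(vals), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}
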