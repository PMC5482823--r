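# Core data model: validated FPKM matrix, gene annotation, sample metadata,
# analysis configuration, and delimited-text loaders.

BIOTYPE_GROUPS <- c("protein_coding", "ncRNA", "pseudogene", "other")

#' Analysis configuration
#'
#' Bundles every threshold used by the downstream stages. Defaults follow the
#' conventions of multi-tissue FPKM atlases: a gene is *expressed* at
#' FPKM >= 0.1, log transformation is `log2(FPKM + 1)` after dropping all-zero
#' rows, differential calls require BH FDR < 0.05 and a two-fold change, and
#' housekeeping/reference selection uses the two-tier stability criteria
#' (FPKM > 1 / SD of log2 tissue means < 1 / no tissue deviating by >= 2 log2
#' units, tightened to FPKM > 50 / SD < 0.5 / deviation < 1 for the reference
#' tier).
#'
#' @param expressed_threshold FPKM at or above which a gene counts as
#'   expressed in a sample (the `>=` convention is applied consistently).
#' @param log_pseudocount Pseudocount added before `log2` transformation.
#' @param fc_pseudocount Pseudocount added to linear-scale group means before
#'   forming fold-change ratios (kept separate from `log_pseudocount` so that
#'   ratios remain meaningful at low expression).
#' @param deg_alpha BH false-discovery-rate level for differential calls.
#' @param deg_fc Minimum linear fold change for a differential call.
#' @param ts_fc_grid Fold-change grid for tissue-specific calling.
#' @param ts_fc_default Grid member used for the headline tissue-specific set.
#' @param sex_fc Fold cutoff for sex-dominated calling.
#' @param hk_min_fpkm,hk_max_sd_log2,hk_max_dev_log2 Housekeeping tier:
#'   minimum FPKM in every sample (strict `>`), maximum SD of per-tissue mean
#'   log2 expression (strict `<`), maximum absolute deviation of any tissue
#'   mean from the cross-tissue average in log2 units (strict `<`).
#' @param ref_min_fpkm,ref_max_sd_log2,ref_max_dev_log2 Reference tier; must
#'   be at least as strict as the housekeeping tier.
#' @param rng_seed Integer seed recorded for pipeline runs.
#' @return A list of class `bm_config`.
#' @export
analysis_config <- function(expressed_threshold = 0.1,
                            log_pseudocount = 1,
                            fc_pseudocount = 0.01,
                            deg_alpha = 0.05,
                            deg_fc = 2,
                            ts_fc_grid = c(2, 4, 8, 16, 32),
                            ts_fc_default = 4,
                            sex_fc = 2,
                            hk_min_fpkm = 1,
                            hk_max_sd_log2 = 1,
                            hk_max_dev_log2 = 2,
                            ref_min_fpkm = 50,
                            ref_max_sd_log2 = 0.5,
                            ref_max_dev_log2 = 1,
                            rng_seed = 1L) {
  cfg <- list(
    expressed_threshold = expressed_threshold,
    log_pseudocount = log_pseudocount,
    fc_pseudocount = fc_pseudocount,
    deg_alpha = deg_alpha,
    deg_fc = deg_fc,
    ts_fc_grid = sort(ts_fc_grid),
    ts_fc_default = ts_fc_default,
    sex_fc = sex_fc,
    hk_min_fpkm = hk_min_fpkm,
    hk_max_sd_log2 = hk_max_sd_log2,
    hk_max_dev_log2 = hk_max_dev_log2,
    ref_min_fpkm = ref_min_fpkm,
    ref_max_sd_log2 = ref_max_sd_log2,
    ref_max_dev_log2 = ref_max_dev_log2,
    rng_seed = as.integer(rng_seed)
  )
  thr <- unlist(cfg[setdiff(names(cfg), c("rng_seed", "ts_fc_grid"))])
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stopf("all thresholds must be finite and > 0")
  }
  if (any(cfg$ts_fc_grid <= 0)) stopf("ts_fc_grid must be positive")
  if (!(ts_fc_default %in% cfg$ts_fc_grid)) {
    stopf("ts_fc_default (%s) must be a member of ts_fc_grid", ts_fc_default)
  }
  if (cfg$ref_min_fpkm < cfg$hk_min_fpkm ||
      cfg$ref_max_sd_log2 > cfg$hk_max_sd_log2 ||
      cfg$ref_max_dev_log2 > cfg$hk_max_dev_log2) {
    stopf("reference-tier criteria must be at least as strict as housekeeping criteria")
  }
  structure(cfg, class = "bm_config")
}

#' Validate an FPKM expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) with unique row and column names, all values finite, non-negative
#' and non-missing. Missing cells are illegal: an absent FPKM cannot be told
#' apart from zero, so a complete matrix is required.
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @return The validated matrix, invisibly usable as-is.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("expression matrix must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) stopf("expression matrix needs row and column names")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) stopf("duplicate gene id(s): %s", fmt_ids(dup))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup)) stopf("duplicate sample id(s): %s", fmt_ids(dup))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stopf("invalid FPKM value %s at gene '%s', sample '%s' (%d offending cell(s))",
          format(values[i, j]), gid[i], sid[j], nrow(bad))
  }
  values
}

#' Validate a gene annotation table
#'
#' Requires columns `gene_id`, `symbol`, `biotype`, `chromosome`. Fine-grained
#' biotype labels (e.g. Ensembl's `lincRNA`, `processed_pseudogene`) are
#' mapped onto the four-way grouping `protein_coding` / `ncRNA` /
#' `pseudogene` / `other` via the shipped mapping table; unmapped labels are
#' an error, never silently "other". The mapped group is stored in a
#' `biotype_group` column.
#'
#' @param annotation data.frame with the required columns.
#' @param mapping Optional two-column data.frame (`biotype`, `group`)
#'   overriding [biotype_groups()].
#' @return The annotation with a validated `biotype_group` column.
#' @export
gene_annotation <- function(annotation, mapping = biotype_groups()) {
  need <- c("gene_id", "symbol", "biotype", "chromosome")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stopf("annotation lacks column(s): %s", fmt_ids(miss))
  dup <- unique(annotation$gene_id[duplicated(annotation$gene_id)])
  if (length(dup)) stopf("duplicate gene id(s) in annotation: %s", fmt_ids(dup))
  annotation$biotype_group <- map_biotypes(annotation$biotype, mapping)
  annotation
}

#' Shipped fine-biotype to four-group mapping table
#'
#' @return data.frame with columns `biotype` and `group`.
#' @export
biotype_groups <- function() {
  path <- system.file("extdata", "biotype_groups.tsv", package = "bodymapr",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Map fine biotype labels onto the four-way grouping
#'
#' @param biotype Character vector of biotype labels.
#' @param mapping data.frame(`biotype`, `group`).
#' @return Character vector of groups, one of
#'   `protein_coding`, `ncRNA`, `pseudogene`, `other`.
#' @export
map_biotypes <- function(biotype, mapping = biotype_groups()) {
  idx <- match(biotype, mapping$biotype)
  if (anyNA(idx)) {
    stopf("unmapped biotype label(s): %s", fmt_ids(unique(biotype[is.na(idx)])))
  }
  grp <- mapping$group[idx]
  bad <- setdiff(unique(grp), BIOTYPE_GROUPS)
  if (length(bad)) stopf("mapping table assigns unknown group(s): %s", fmt_ids(bad))
  grp
}

#' Validate a sample metadata table
#'
#' Requires columns `sample_id`, `tissue`, `sex`, `individual` and an optional
#' logical `sexual_tissue` column (derived as "tissue observed in one sex
#' only" when absent). Each sexual tissue must appear in exactly one sex.
#'
#' @param metadata data.frame with the required columns.
#' @return Validated metadata with a logical `sexual_tissue` column.
#' @export
sample_metadata <- function(metadata) {
  need <- c("sample_id", "tissue", "sex", "individual")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stopf("metadata lacks column(s): %s", fmt_ids(miss))
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup)) stopf("duplicate sample id(s) in metadata: %s", fmt_ids(dup))
  bad <- setdiff(unique(metadata$sex), c("female", "male"))
  if (length(bad)) stopf("sex must be 'female' or 'male'; found: %s", fmt_ids(bad))
  sexes_per_tissue <- tapply(metadata$sex, metadata$tissue,
                             function(s) length(unique(s)))
  if (is.null(metadata$sexual_tissue)) {
    metadata$sexual_tissue <- sexes_per_tissue[metadata$tissue] == 1L
  } else {
    declared <- tapply(metadata$sexual_tissue, metadata$tissue, unique)
    if (any(lengths(declared) != 1L)) {
      stopf("sexual_tissue flag inconsistent within a tissue")
    }
    both <- names(sexes_per_tissue)[sexes_per_tissue == 2L]
    offending <- intersect(both, names(declared)[unlist(declared)])
    if (length(offending)) {
      stopf("sexual tissue(s) observed in both sexes: %s", fmt_ids(offending))
    }
  }
  metadata$sexual_tissue <- as.logical(metadata$sexual_tissue)
  metadata
}

#' Load and validate a dataset triple from delimited text
#'
#' Reads a genes-by-samples FPKM matrix (first column the gene id), a gene
#' annotation table and a sample metadata table. Genes present in the matrix
#' but missing from the annotation are rejected (dropped) and reported in the
#' returned `rejected_genes`; any mismatch between matrix samples and
#' metadata samples is a hard error listing the symmetric difference.
#' Row and column order is preserved from the input files.
#'
#' @param matrix_path,annotation_path,metadata_path Paths to delimited files
#'   with header rows.
#' @param sep Field separator; tab by default, pass `","` for CSV.
#' @return list of class `bm_dataset` with elements `matrix`, `annotation`,
#'   `metadata`, `rejected_genes`.
#' @export
load_dataset <- function(matrix_path, annotation_path, metadata_path,
                         sep = "\t") {
  for (p in c(matrix_path, annotation_path, metadata_path)) {
    if (!file.exists(p)) stopf("input file not found: %s", p)
  }
  raw <- read.delim(matrix_path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  gid <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 2L, as.numeric))),
                 arr.ind = TRUE)
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stopf("non-numeric FPKM at gene '%s', sample '%s'", gid[i], colnames(vals)[j])
  }
  rownames(vals) <- gid
  mat <- expression_matrix(vals)
  ann <- gene_annotation(read.delim(annotation_path, sep = sep,
                                    stringsAsFactors = FALSE))
  meta <- sample_metadata(read.delim(metadata_path, sep = sep,
                                     stringsAsFactors = FALSE))

  only_matrix <- setdiff(colnames(mat), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(mat))
  if (length(only_matrix) || length(only_meta)) {
    stopf("matrix/metadata sample mismatch; only in matrix: [%s]; only in metadata: [%s]",
          fmt_ids(only_matrix), fmt_ids(only_meta))
  }
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  rejected <- setdiff(rownames(mat), ann$gene_id)
  if (length(rejected)) {
    message(sprintf("rejecting %d unannotated gene(s): %s",
                    length(rejected), fmt_ids(rejected)))
    mat <- mat[setdiff(rownames(mat), rejected), , drop = FALSE]
  }
  ann <- ann[match(rownames(mat), ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL

  structure(list(matrix = mat, annotation = ann, metadata = meta,
                 rejected_genes = rejected),
            class = "bm_dataset")
}

#' Write a dataset triple as delimited text
#'
#' Emits the same dialect [load_dataset()] reads: tab-separated, matrix with
#' a leading `gene_id` column, annotation and metadata with named columns.
#'
#' @param matrix,annotation,metadata Dataset components.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param sep Field separator.
#' @return Invisibly, named vector of the three file paths.
#' @export
write_dataset <- function(matrix, annotation, metadata, dir, prefix = "dataset",
                          sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, paste0(prefix, "_fpkm.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv"))
  )
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  fmt <- as.data.frame(apply(matrix, 2L, function(x) sprintf("%.17g", x)),
                       check.names = FALSE)
  write_tsv(cbind(data.frame(gene_id = rownames(matrix)), fmt),
            paths["matrix"], sep = sep)
  ann <- annotation
  ann$biotype_group <- NULL
  write_tsv(ann, paths["annotation"], sep = sep)
  write_tsv(metadata, paths["metadata"], sep = sep)
  invisible(paths)
}

write_tsv <- function(df, path, sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Count genes per four-way biotype group
#'
#' The four groups partition the annotation: counts always sum to the number
#' of annotated genes.
#'
#' @param annotation Annotation validated by [gene_annotation()] (or a raw
#'   table, which is validated first).
#' @return Named integer vector over the four groups with attribute `total`.
#' @export
validate_partition <- function(annotation) {
  if (!nrow(annotation)) stopf("annotation is empty")
  if (is.null(annotation$biotype_group)) annotation <- gene_annotation(annotation)
  counts <- vapply(BIOTYPE_GROUPS,
                   function(g) sum(annotation$biotype_group == g), integer(1L))
  stopifnot(sum(counts) == nrow(annotation))
  attr(counts, "total") <- nrow(annotation)
  counts
}
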