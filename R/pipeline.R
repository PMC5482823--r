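# One-command orchestration: landscape -> clustering/outliers -> optional
# outlier exclusion -> DEG / tissue-specific / sex-dominated -> housekeeping
# -> ERCC QC, with a JSON config, a run manifest and a small CLI.

default_run_config <- function() {
  list(
    inputs = list(matrix = NULL, annotation = NULL, metadata = NULL,
                  ercc = NULL, mix = NULL, homology = NULL, foreign_hk = NULL),
    out_dir = "bodymap_results",
    analysis = list(),
    stages = list(landscape = TRUE, clustering = TRUE, differential = TRUE,
                  housekeeping = TRUE, ercc_qc = TRUE),
    exclude_outliers = FALSE
  )
}

read_run_config <- function(config) {
  cfg <- default_run_config()
  user <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config
  }
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      utils::modifyList(cfg[[k]], user[[k]])
    } else {
      user[[k]]
    }
  }
  cfg
}

log_line <- function(logfile, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message("[bodymapr] ", msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: expression landscape (flags, biotype and per-tissue
#' summaries), log transform, sample clustering with nearest-neighbour
#' outlier flagging, an optional exclusion pass (dropping *all* samples of
#' any tissue containing a flagged sample — the conservative whole-tissue
#' removal — before the downstream stages), pairwise DEG counts,
#' tissue-specific and sex-dominated calling, housekeeping/reference
#' selection with chromosome distribution (plus homology overlap when a
#' mapping and foreign list are supplied), and ERCC spike-in QC when a spike
#' reference and mix assignment are supplied. Each stage writes TSV artifacts
#' to `out_dir` and the run ends with a JSON manifest (config snapshot, input
#' digests, per-stage row counts, seed, package version). Stages are
#' individually skippable via the `stages` config block; any stage error
#' aborts with the stage name.
#'
#' @param config Path to a JSON config file, or an equivalent list. Keys:
#'   `inputs` (`matrix`, `annotation`, `metadata` paths; optional `ercc`,
#'   `mix`, `homology`, `foreign_hk`), `out_dir`, `analysis` (overrides for
#'   [analysis_config()]), `stages`, `exclude_outliers`.
#' @param out_dir Optional override of the config's output directory.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  unlink(logfile)
  acfg <- do.call(analysis_config, cfg$analysis)

  stage <- function(name, expr) {
    log_line(logfile, "stage %s", name)
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                   seed = acfg$rng_seed,
                   version = as.character(utils::packageVersion("bodymapr")),
                   inputs = list(), stages = list())
  in_paths <- Filter(Negate(is.null), cfg$inputs)
  manifest$inputs <- lapply(in_paths, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })

  ds <- stage("load", load_dataset(cfg$inputs$matrix, cfg$inputs$annotation,
                                   cfg$inputs$metadata))
  # spike rows live in the raw matrix file, not the annotated gene set
  mat <- ds$matrix
  meta <- ds$metadata
  manifest$stages$load <- list(n_genes = nrow(mat), n_samples = ncol(mat),
                               n_rejected = length(ds$rejected_genes))

  if (isTRUE(cfg$stages$landscape)) {
    stage("landscape", {
      flags <- flag_expressed(mat, acfg$expressed_threshold)
      write_tsv(flags, file.path(cfg$out_dir, "expression_flags.tsv"))
      bs <- biotype_summary(flags, ds$annotation)
      write_tsv(bs, file.path(cfg$out_dir, "biotype_summary.tsv"))
      pt <- expressed_per_tissue(mat, meta, acfg$expressed_threshold)
      write_tsv(pt, file.path(cfg$out_dir, "expressed_per_tissue.tsv"))
      manifest$stages$landscape <- list(
        n_expressed = sum(flags$expressed),
        n_ubiquitous = sum(flags$ubiquitous))
    })
  }

  logm <- make_log_matrix(mat, acfg$log_pseudocount)
  if (isTRUE(cfg$stages$clustering)) {
    stage("clustering", {
      rep_ <- cluster_samples(logm)
      merges <- data.frame(step = seq_len(nrow(rep_$hclust$merge)),
                           left = rep_$hclust$merge[, 1L],
                           right = rep_$hclust$merge[, 2L],
                           height = rep_$hclust$height)
      write_tsv(merges, file.path(cfg$out_dir, "cluster_merges.tsv"))
      fl <- flag_outliers(rep_, meta)
      write_tsv(fl, file.path(cfg$out_dir, "outlier_flags.tsv"))
      flagged_tissues <- unique(fl$tissue[fl$flagged])
      manifest$stages$clustering <- list(
        n_flagged = sum(fl$flagged), flagged_tissues = flagged_tissues)
      if (isTRUE(cfg$exclude_outliers) && length(flagged_tissues)) {
        keep <- !(meta$tissue %in% flagged_tissues)
        log_line(logfile, "excluding tissue(s) with flagged samples: %s (%d samples dropped)",
                 fmt_ids(flagged_tissues), sum(!keep))
        meta <- meta[keep, , drop = FALSE]
        mat <- mat[, meta$sample_id, drop = FALSE]
        logm <- make_log_matrix(mat, acfg$log_pseudocount)
        manifest$stages$clustering$n_samples_after_exclusion <- ncol(mat)
      }
    })
  }

  if (isTRUE(cfg$stages$differential)) {
    stage("differential", {
      dc <- deg_count_matrix(logm, meta, acfg$deg_alpha, acfg$deg_fc,
                             acfg$fc_pseudocount)
      write_tsv(data.frame(tissue = rownames(dc$up), dc$up, check.names = FALSE),
                file.path(cfg$out_dir, "deg_counts_up.tsv"))
      write_tsv(data.frame(tissue = rownames(dc$down), dc$down, check.names = FALSE),
                file.path(cfg$out_dir, "deg_counts_down.tsv"))
      ts <- tissue_specific(mat, meta, acfg$ts_fc_grid, acfg$fc_pseudocount,
                            acfg$expressed_threshold)
      def <- ts$calls[[as.character(acfg$ts_fc_default)]]
      write_tsv(def, file.path(cfg$out_dir, "tissue_specific_genes.tsv"))
      sx <- sex_dominated_all(mat, meta, acfg$sex_fc, acfg$fc_pseudocount)
      sx_tab <- do.call(rbind, lapply(sx, function(r) {
        if (!length(r$female_dominated) && !length(r$male_dominated)) return(NULL)
        data.frame(tissue = r$tissue,
                   gene_id = c(r$female_dominated, r$male_dominated),
                   dominant_sex = c(rep("female", length(r$female_dominated)),
                                    rep("male", length(r$male_dominated))),
                   stringsAsFactors = FALSE)
      }))
      if (is.null(sx_tab)) {
        sx_tab <- data.frame(tissue = character(0), gene_id = character(0),
                             dominant_sex = character(0))
      }
      write_tsv(sx_tab, file.path(cfg$out_dir, "sex_dominated_genes.tsv"))
      manifest$stages$differential <- list(
        n_tissue_specific = nrow(def), n_sex_dominated = nrow(sx_tab),
        n_samples = ncol(mat))
    })
  }

  if (isTRUE(cfg$stages$housekeeping)) {
    stage("housekeeping", {
      st <- stability_stats(mat, meta)
      hk <- identify_housekeeping(st, acfg)
      rf <- select_reference_genes(st, acfg)
      write_tsv(hk$diagnostics, file.path(cfg$out_dir, "housekeeping_diagnostics.tsv"))
      write_tsv(data.frame(gene_id = hk$genes),
                file.path(cfg$out_dir, "housekeeping_genes.tsv"))
      write_tsv(data.frame(gene_id = rf$genes),
                file.path(cfg$out_dir, "reference_genes.tsv"))
      cd <- chromosome_distribution(hk$genes, ds$annotation)
      write_tsv(cd, file.path(cfg$out_dir, "housekeeping_chromosomes.tsv"))
      manifest$stages$housekeeping <- list(
        n_housekeeping = length(hk$genes), n_reference = length(rf$genes),
        n_samples = ncol(mat))
      if (!is.null(cfg$inputs$homology) && !is.null(cfg$inputs$foreign_hk)) {
        mapping <- read.delim(cfg$inputs$homology, stringsAsFactors = FALSE)
        foreign <- readLines(cfg$inputs$foreign_hk)
        ov <- homology_overlap(hk$genes, foreign, mapping)
        jsonlite::write_json(ov[c("overlap", "n_mapped_foreign", "n_own",
                                  "pct_of_mapped_foreign", "pct_of_own")],
                             file.path(cfg$out_dir, "homology_overlap.json"),
                             auto_unbox = TRUE, digits = NA)
        manifest$stages$housekeeping$homology_overlap <- ov$overlap
      }
    })
  }

  if (isTRUE(cfg$stages$ercc_qc) && !is.null(cfg$inputs$ercc) &&
      !is.null(cfg$inputs$mix)) {
    stage("ercc_qc", {
      raw <- read.delim(cfg$inputs$matrix, check.names = FALSE,
                        stringsAsFactors = FALSE)
      full <- as.matrix(raw[, -1L, drop = FALSE])
      rownames(full) <- raw[[1L]]
      ref <- read.delim(cfg$inputs$ercc, stringsAsFactors = FALSE)
      mixdf <- read.delim(cfg$inputs$mix, stringsAsFactors = FALSE)
      mixmap <- setNames(mixdf$mix, mixdf$sample_id)
      qc <- ercc_qc(full, ref, mixmap)
      write_tsv(qc, file.path(cfg$out_dir, "ercc_qc.tsv"))
      manifest$stages$ercc_qc <- list(
        n_flagged = sum(qc$flag != "ok"), n_samples = nrow(qc))
    })
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line(logfile, "done; artifacts in %s", cfg$out_dir)
  invisible(manifest)
}

# --- minimal CLI ------------------------------------------------------------

parse_cli_args <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

cli_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset with truth labels,
#' spike-in reference and mix map), `landscape`, `deg`, `tsg`, `sexdom`,
#' `housekeeping`, `erccqc`, and `run-all` (JSON config). Installed as the
#' `bodymap` script under the package `exec/` directory; tests call this
#' function directly.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` when run as a script).
#' @return Invisibly, the main artifact of the subcommand.
#' @export
bodymap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stopf(paste("usage: bodymap <simulate|landscape|deg|tsg|sexdom|",
                "housekeeping|erccqc|run-all> [--flag value ...]"))
  }
  cmd <- args[[1L]]
  flags <- parse_cli_args(args[-1L])
  out <- flags$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  load_triple <- function() {
    load_dataset(flags$matrix, flags$annotation %||% flags$anno, flags$meta)
  }

  res <- switch(
    cmd,
    "simulate" = {
      sc <- simulation_config(
        n_genes = as.integer(cli_num(flags, "n_genes", 2000)),
        seed = as.integer(cli_num(flags, "seed", 1)))
      sim <- generate_dataset(sc)
      ref <- generate_ercc_reference(sc$seed)
      mix <- setNames(rep(c("Mix1", "Mix2"),
                          length.out = ncol(sim$matrix)),
                      colnames(sim$matrix))
      mat <- if (isTRUE(flags$spike)) {
        spike_dataset(sim$matrix, ref, mix, noise_sd_log2 = 0.3,
                      seed = sc$seed, ercc_fraction = sc$ercc_fraction)
      } else {
        sim$matrix
      }
      write_dataset(mat, sim$annotation, sim$metadata, out, prefix = "sim")
      write_tsv(sim$truth, file.path(out, "sim_truth.tsv"))
      write_tsv(ref, file.path(out, "sim_ercc_reference.tsv"))
      write_tsv(data.frame(sample_id = names(mix), mix = mix),
                file.path(out, "sim_mix_assignment.tsv"))
      invisible(sim)
    },
    "landscape" = {
      ds <- load_triple()
      thr <- cli_num(flags, "threshold", 0.1)
      flags_df <- flag_expressed(ds$matrix, thr)
      write_tsv(flags_df, file.path(out, "expression_flags.tsv"))
      write_tsv(biotype_summary(flags_df, ds$annotation),
                file.path(out, "biotype_summary.tsv"))
      write_tsv(expressed_per_tissue(ds$matrix, ds$metadata, thr),
                file.path(out, "expressed_per_tissue.tsv"))
      invisible(flags_df)
    },
    "deg" = {
      ds <- load_triple()
      logm <- make_log_matrix(ds$matrix)
      pair <- strsplit(flags$pair, ",", fixed = TRUE)[[1L]]
      if (length(pair) != 2L) stopf("--pair expects 'tissueA,tissueB'")
      tab <- pairwise_deg(logm, ds$metadata, pair[1L], pair[2L],
                          alpha = cli_num(flags, "alpha", 0.05),
                          fc = cli_num(flags, "fc", 2))
      write_tsv(tab, file.path(out, sprintf("deg_%s_vs_%s.tsv",
                                            pair[1L], pair[2L])))
      invisible(tab)
    },
    "tsg" = {
      ds <- load_triple()
      ts <- tissue_specific(ds$matrix, ds$metadata)
      f <- as.character(cli_num(flags, "fc", 4))
      write_tsv(ts$calls[[f]], file.path(out, "tissue_specific_genes.tsv"))
      invisible(ts)
    },
    "sexdom" = {
      ds <- load_triple()
      sx <- sex_dominated_all(ds$matrix, ds$metadata,
                              fc = cli_num(flags, "fc", 2))
      tabs <- do.call(rbind, lapply(sx, function(r) {
        data.frame(tissue = r$tissue,
                   gene_id = c(r$female_dominated, r$male_dominated),
                   dominant_sex = c(rep("female", length(r$female_dominated)),
                                    rep("male", length(r$male_dominated))))
      }))
      write_tsv(tabs, file.path(out, "sex_dominated_genes.tsv"))
      invisible(sx)
    },
    "housekeeping" = {
      ds <- load_triple()
      st <- stability_stats(ds$matrix, ds$metadata)
      acfg <- analysis_config()
      res <- if (isTRUE(flags$ref_tier)) select_reference_genes(st, acfg)
             else identify_housekeeping(st, acfg)
      write_tsv(res$diagnostics, file.path(out, "stability_diagnostics.tsv"))
      write_tsv(data.frame(gene_id = res$genes),
                file.path(out, paste0(res$tier, "_genes.tsv")))
      invisible(res)
    },
    "erccqc" = {
      raw <- read.delim(flags$matrix, check.names = FALSE,
                        stringsAsFactors = FALSE)
      mat <- as.matrix(raw[, -1L, drop = FALSE])
      rownames(mat) <- raw[[1L]]
      ref <- read.delim(flags$ercc, stringsAsFactors = FALSE)
      mixdf <- read.delim(flags$mix, stringsAsFactors = FALSE)
      qc <- ercc_qc(mat, ref, setNames(mixdf$mix, mixdf$sample_id))
      write_tsv(qc, file.path(out, "ercc_qc.tsv"))
      invisible(qc)
    },
    "run-all" = run_all(flags$config, out_dir = flags$out),
    stopf("unknown subcommand '%s'", cmd)
  )
  invisible(res)
}
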