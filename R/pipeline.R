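# Orchestration: configuration, the end-to-end synthetic/real run,
# run manifest, and the command-line entry point.

# family census used by the synthetic world: 14 defense-gene families
# totalling 447 genes, the size distribution the analysis was designed for
default_family_sizes <- c(
  "PR-1" = 18, "PR-2" = 50, "PR-3" = 22, "PR-4" = 5, "PR-5" = 36,
  "PR-6" = 3, "PR-7" = 72, "PR-8" = 10, "PR-9" = 110, "PR-10" = 21,
  "PR-11" = 5, "PR-14" = 30, "PR-15/16" = 59, "PR-17" = 6)

#' Default pipeline configuration
#'
#' All analysis thresholds are surfaced as named keys with their standard
#' values: DEG fold-change cutoff 1 (log2), FDR 0.05, low-count filter 20,
#' expansion minimum size 3, correlation gate 10 shared DEGs, boxplot
#' constant 2.0.
#'
#' @param seed integer seed driving every stage's randomness.
#' @param n_genotypes number of genotype time courses simulated.
#' @param ... overrides for [sim_config()] fields.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, n_genotypes = 4L, ...) {
  list(
    seed = as.integer(seed),
    thresholds = list(lfc = 1, fdr = 0.05, low_count = 20,
                      expansion_min_size = 3, min_shared = 10,
                      outlier_k = 2.0, max_gap_bases = 1e5,
                      max_intervening = 5),
    n_genotypes = n_genotypes,
    sim = c(list(seed = as.integer(seed)), list(...))
  )
}

#' Read a pipeline configuration file (YAML or JSON)
#' @param path config file; keys mirror [default_config()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- default_config(seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  utils::modifyList(base, cfg)
}

# write a table with the manifest hash in a header comment
write_stage_table <- function(df, path, manifest_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# manifest: %s", manifest_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic world
#'
#' Sequences simulate -> call-degs -> classify -> structure ->
#' cross-stress -> qpcr with all randomness flowing from the single config
#' seed, and writes tab-separated stage outputs plus a machine-readable
#' run manifest (config snapshot, seed, per-stage row counts, output
#' checksums). Re-running with an identical config and seed reproduces
#' identical outputs byte for byte.
#'
#' @param config list from [default_config()] or [read_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("prstress_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  sim_args <- config$sim
  scfg <- do.call(sim_config, sim_args)
  manifest_hash <- substr(tools::md5sum(
    local({f <- tempfile(); writeLines(
      jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), f); f})), 1, 12)

  # --- simulate + call DEGs per genotype -------------------------------
  genotypes <- paste0("G", seq_len(config$n_genotypes))
  degs_list <- list(); truths <- list()
  for (i in seq_along(genotypes)) {
    gcfg <- scfg
    gcfg$seed <- scfg$seed + 100L * i
    gcfg$program_seed <- scfg$seed  # shared responder set across genotypes
    sim <- simulate_timecourse_counts(gcfg, condition = genotypes[i])
    truths[[genotypes[i]]] <- sim$truth
    degs_list[[genotypes[i]]] <- call_degs(
      sim$counts, count_threshold = th$low_count,
      lfc_threshold = th$lfc, fdr_threshold = th$fdr)
  }
  degs <- do.call(rbind, degs_list)
  class(degs) <- c("pr_degs", "data.frame")

  # --- hormones --------------------------------------------------------
  hcfg <- scfg; hcfg$seed <- scfg$seed + 1000L
  hsim <- simulate_hormone_pair(hcfg)
  sa_degs <- call_degs(hsim$sa, count_threshold = th$low_count,
                       lfc_threshold = th$lfc, fdr_threshold = th$fdr)
  ja_degs <- call_degs(hsim$ja, count_threshold = th$low_count,
                       lfc_threshold = th$lfc, fdr_threshold = th$fdr)

  # --- classification --------------------------------------------------
  assignments <- classify_programs(degs, sa = sa_degs, ja = ja_degs,
                                   genotypes = genotypes)
  fam_sizes <- default_family_sizes
  n <- scfg$n_genes
  fam_vec <- rep(names(fam_sizes), fam_sizes)
  fam_vec <- rep_len(fam_vec, n)
  catalog <- gene_catalog(gene_id = sprintf("g%04d", seq_len(n)),
                          family = fam_vec)
  summary_tbl <- program_summary(assignments, catalog)
  coreg <- assignments$gene_id[!is.na(assignments$hormone_program) &
                                 assignments$hormone_program == "co_regulated"]
  sa_prof <- consolidate_profile(sa_degs, "SA")
  ja_prof <- consolidate_profile(ja_degs, "JA")
  coreg_res <- NULL
  shared <- intersect(intersect(coreg, sa_prof$gene_id), ja_prof$gene_id)
  if (length(shared) >= 3) {
    coreg_res <- coreg_correlation(
      sa_prof$mean_log2FC[match(shared, sa_prof$gene_id)],
      ja_prof$mean_log2FC[match(shared, ja_prof$gene_id)])
  }

  # --- family structure ------------------------------------------------
  fsim <- simulate_family_structure(scfg)
  expansions <- do.call(rbind, lapply(names(fsim$trees), function(f)
    detect_expansions(fsim$trees[[f]], scfg$focal_species,
                      min_size = th$expansion_min_size, family = f)))
  clusters <- detect_physical_clusters(fsim$catalog,
                                       max_gap_bases = th$max_gap_bases,
                                       max_intervening = th$max_intervening)
  clu_sum <- cluster_summary(clusters, fsim$catalog)
  deg_hist <- stats::setNames(rep(TRUE, length(unique(degs$gene_id[degs$status != "ns"]))),
                              unique(degs$gene_id[degs$status != "ns"]))
  names_tbl <- do.call(rbind, lapply(names(fsim$trees), function(f)
    assign_nomenclature(fsim$trees[[f]], f, deg_hist,
                        focal_species = scfg$focal_species)))

  # --- cross-stress ----------------------------------------------------
  wf_prof <- consolidate_profile(degs_list[[1]], genotypes[1])
  corr_wf_sa <- correlate_stresses(wf_prof, sa_prof, min_shared = th$min_shared,
                                   k = th$outlier_k)
  corr_wf_ja <- correlate_stresses(wf_prof, ja_prof, min_shared = th$min_shared,
                                   k = th$outlier_k)
  attribution <- family_attribution(list(WF = wf_prof, SA = sa_prof, JA = ja_prof),
                                    catalog)

  # --- qPCR ------------------------------------------------------------
  set.seed(scfg$seed + 2000L)
  val_genes <- utils::head(wf_prof$gene_id[order(-abs(wf_prof$mean_log2FC))], 12)
  true_lfc <- wf_prof$mean_log2FC[match(val_genes, wf_prof$gene_id)]
  ct <- simulate_ct_table(val_genes, true_lfc, n_replicates = 3, noise_sd = 0.5)
  qpcr <- delta_delta_ct(ct, ref_gene = "UBQ",
                         treated_condition = "treated",
                         control_condition = "control")
  concord <- platform_concordance(
    qpcr$log2FC[match(val_genes, qpcr$gene)], true_lfc)

  # --- heatmap-ready matrix: gene x condition mean log2FC --------------
  prof_all <- lapply(degs_list, function(d) consolidate_profile(d))
  hm_genes <- sort(unique(unlist(lapply(prof_all, `[[`, "gene_id"))))
  heat <- sapply(prof_all, function(p)
    p$mean_log2FC[match(hm_genes, p$gene_id)])
  heat_df <- data.frame(gene_id = hm_genes, heat, check.names = FALSE)

  # --- write outputs + manifest ---------------------------------------
  files <- list(
    degs = file.path(out_dir, "degs.tsv"),
    programs = file.path(out_dir, "programs.tsv"),
    names = file.path(out_dir, "names.tsv"),
    expansions = file.path(out_dir, "expansions.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    heatmap = file.path(out_dir, "log2fc_matrix.tsv"),
    qpcr = file.path(out_dir, "qpcr.tsv"))
  write_stage_table(as.data.frame(degs), files$degs, manifest_hash)
  write_stage_table(assignments, files$programs, manifest_hash)
  write_stage_table(names_tbl, files$names, manifest_hash)
  write_stage_table(expansions, files$expansions, manifest_hash)
  write_stage_table(clusters, files$clusters, manifest_hash)
  write_stage_table(heat_df, files$heatmap, manifest_hash)
  write_stage_table(qpcr, files$qpcr, manifest_hash)
  manifest <- list(
    package = "prstress",
    version = as.character(utils::packageVersion("prstress")),
    seed = config$seed,
    manifest_hash = manifest_hash,
    config = config,
    stage_rows = list(degs = nrow(degs), programs = nrow(assignments),
                      names = nrow(names_tbl), expansions = nrow(expansions),
                      clusters = nrow(clusters), qpcr = nrow(qpcr)),
    checksums = as.list(tools::md5sum(unlist(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(degs = degs, sa_degs = sa_degs, ja_degs = ja_degs,
                 assignments = assignments, summary = summary_tbl,
                 coreg_correlation = coreg_res, truths = truths,
                 hormone_truth = hsim$truth, structure = fsim,
                 expansions = expansions, clusters = clusters,
                 cluster_summary = clu_sum, nomenclature = names_tbl,
                 correlations = list(WF_SA = corr_wf_sa, WF_JA = corr_wf_ja),
                 attribution = attribution, qpcr = qpcr,
                 concordance = concord, manifest = manifest,
                 out_dir = out_dir))
}

#' Simulate a comparative-Ct qPCR table from known log2 fold changes
#'
#' Reference-gene Ct is flat across samples; target-gene Ct shifts by
#' \code{-log2FC} between control and treated, plus Gaussian replicate
#' noise.
#'
#' @param genes gene ids.
#' @param log2fc true log2 fold changes, one per gene.
#' @param n_replicates replicates per condition.
#' @param noise_sd Ct measurement noise (cycles); 0 gives exact recovery.
#' @param ref_gene reference gene id (default \code{"UBQ"}).
#' @return Ct table data.frame (\code{gene}, \code{sample},
#'   \code{condition}, \code{Ct}).
#' @export
simulate_ct_table <- function(genes, log2fc, n_replicates = 3,
                              noise_sd = 0.5, ref_gene = "UBQ") {
  conds <- c("control", "treated")
  samples <- paste0(rep(conds, each = n_replicates), "_r",
                    rep(seq_len(n_replicates), 2))
  cond_of <- rep(conds, each = n_replicates)
  rows <- list()
  for (s in seq_along(samples)) {
    rows[[length(rows) + 1]] <- data.frame(
      gene = ref_gene, sample = samples[s], condition = cond_of[s],
      Ct = 18, stringsAsFactors = FALSE)
    for (g in seq_along(genes)) {
      base <- 25
      shift <- if (cond_of[s] == "treated") -log2fc[g] else 0
      rows[[length(rows) + 1]] <- data.frame(
        gene = genes[g], sample = samples[s], condition = cond_of[s],
        Ct = base + shift + stats::rnorm(1, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' \code{prstress <simulate|call-degs|classify|cross-stress|qpcr|run>
#' [--config config.yml] [--seed N] [--out DIR] ...}. \code{run} executes
#' the full synthetic pipeline; \code{call-degs} takes \code{--counts},
#' \code{--meta} and \code{--condition}; \code{qpcr} takes \code{--ct} and
#' \code{--ref-gene}.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process's).
#' @return exit code 0 on success (invisibly).
#' @export
prstress_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: prstress <simulate|call-degs|classify|cross-stress|qpcr|run> [options]")
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else
    default_config(seed = as.integer(opts$seed %||% 1L))
  if (!is.null(opts$seed)) {
    cfg$seed <- as.integer(opts$seed)
    cfg$sim$seed <- cfg$seed
  }
  out <- opts$out %||% "prstress_out"
  switch(cmd,
    run = {
      run_pipeline(cfg, out_dir = out)
      message("pipeline complete: ", out)
    },
    simulate = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      scfg <- do.call(sim_config, cfg$sim)
      sim <- simulate_timecourse_counts(scfg)
      write_counts(sim$counts, file.path(out, "counts.tsv"))
      utils::write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fsim <- simulate_family_structure(scfg)
      write_catalog(fsim$catalog, file.path(out, "catalog.tsv"))
      for (f in names(fsim$newick)) {
        writeLines(fsim$newick[[f]],
                   file.path(out, paste0("tree_", gsub("[^A-Za-z0-9]", "", f), ".nwk")))
      }
      message("synthetic inputs written: ", out)
    },
    `call-degs` = {
      x <- read_counts(opts$counts, opts$meta)
      keep <- x$meta$condition == opts$condition
      x <- count_matrix(x$counts[, keep, drop = FALSE], x$meta[keep, ])
      degs <- call_degs(x, count_threshold = cfg$thresholds$low_count,
                        lfc_threshold = cfg$thresholds$lfc,
                        fdr_threshold = cfg$thresholds$fdr)
      write_deg_table(degs, opts$out %||% "degs.tsv")
    },
    classify = {
      degs <- read_deg_table(opts$degs)
      res <- classify_programs(degs)
      utils::write.table(res, opts$out %||% "programs.tsv", sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    `cross-stress` = {
      paths <- strsplit(opts$profiles, ",")[[1]]
      profs <- lapply(paths, function(p) {
        d <- utils::read.delim(p, stringsAsFactors = FALSE)
        class(d) <- c("pr_profile", "data.frame"); d
      })
      res <- list()
      for (i in seq_along(profs)) for (j in seq_along(profs)) {
        if (i < j) {
          r <- correlate_stresses(profs[[i]], profs[[j]],
                                  min_shared = cfg$thresholds$min_shared,
                                  k = cfg$thresholds$outlier_k)
          res[[length(res) + 1]] <- data.frame(
            a = r$stress_a, b = r$stress_b, R = r$R, p = r$p,
            n_used = r$n_used, skipped = r$skipped,
            strength = r$strength %||% NA, stringsAsFactors = FALSE)
        }
      }
      utils::write.table(do.call(rbind, res), opts$out %||% "corr.tsv",
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    qpcr = {
      ct <- utils::read.delim(opts$ct, stringsAsFactors = FALSE)
      res <- delta_delta_ct(ct, ref_gene = opts$`ref-gene`,
                            treated_condition = opts$treated %||% "treated",
                            control_condition = opts$control %||% "control")
      utils::write.table(res, opts$out %||% "qpcr.tsv", sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2
      } else {
        opts[[key]] <- TRUE; i <- i + 1
      }
    } else i <- i + 1
  }
  opts
}
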