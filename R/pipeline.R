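#' Configuration of the end-to-end analysis pipeline
#'
#' Collects every stage parameter of the workflow: input mode (synthetic
#' simulation or files on disk), differential-expression thresholds, network
#' construction settings, module classification threshold, strong-edge
#' cutoffs, the guilt-by-association neighbour count, dataset exclusions,
#' output directory and seed.
#'
#' @param input_mode `"simulate"` (default) or `"files"`.
#' @param synthetic A [synthetic_config] (simulate mode).
#' @param datasets Files mode: list of per-dataset lists with elements
#'   `matrix`, `conditions`, `biotypes` (paths) and `id`.
#' @param gmt_file Optional GMT path for enrichment (files mode).
#' @param alpha,fc_threshold Differential-expression cutoffs.
#' @param candidate_powers,r2_target Soft-power selection settings.
#' @param min_module_size Named numeric, minimum module size per biotype
#'   (defaults: mRNA 10, lncRNA 5).
#' @param homogeneity_threshold Module classification threshold (default
#'   0.90; 0.95 is the stricter alternative). Always echoed in the manifest.
#' @param edge_threshold Named numeric, strong-edge |PCC| cutoff per biotype
#'   (defaults: mRNA 0.7, lncRNA 0.5).
#' @param k_neighbors Top correlated mRNAs representing a lncRNA (default 15).
#' @param exclude Dataset ids dropped from the common-module search.
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides `synthetic$seed` in simulate mode).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("simulate", "files"),
                            synthetic = synthetic_config(),
                            datasets = list(),
                            gmt_file = NULL,
                            alpha = 0.05, fc_threshold = 1.5,
                            candidate_powers = 1:20, r2_target = 0.8,
                            min_module_size = c(mRNA = 10, lncRNA = 5),
                            homogeneity_threshold = 0.9,
                            edge_threshold = c(mRNA = 0.7, lncRNA = 0.5),
                            k_neighbors = 15,
                            exclude = character(0),
                            out_dir = "pipeline_out",
                            seed = NULL) {
  input_mode <- match.arg(input_mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha out of range", call. = FALSE)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1", call. = FALSE)
  if (homogeneity_threshold <= 0.5 || homogeneity_threshold >= 1) {
    stop("homogeneity_threshold out of range", call. = FALSE)
  }
  stopifnot(all(c("mRNA", "lncRNA") %in% names(min_module_size)),
            all(c("mRNA", "lncRNA") %in% names(edge_threshold)))
  if (input_mode == "simulate") {
    stopifnot(inherits(synthetic, "synthetic_config"))
    if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  } else if (!length(datasets)) {
    stop("files mode needs at least one dataset entry", call. = FALSE)
  }
  structure(list(input_mode = input_mode, synthetic = synthetic,
                 datasets = datasets, gmt_file = gmt_file,
                 alpha = alpha, fc_threshold = fc_threshold,
                 candidate_powers = as.integer(candidate_powers),
                 r2_target = r2_target,
                 min_module_size = min_module_size,
                 homogeneity_threshold = homogeneity_threshold,
                 edge_threshold = edge_threshold,
                 k_neighbors = as.integer(k_neighbors),
                 exclude = exclude, out_dir = out_dir,
                 seed = if (is.null(seed)) synthetic$seed else as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    syn <- unclass(out$synthetic)
    syn$module_specs <- lapply(syn$module_specs, unclass)
    out$synthetic <- syn
  }
  # named vectors serialise as YAML maps only in list form
  out$min_module_size <- as.list(out$min_module_size)
  out$edge_threshold <- as.list(out$edge_threshold)
  out
}

#' Read and write a pipeline configuration as YAML
#'
#' The YAML form holds only plain values; constructors re-validate on read,
#' so a written configuration round-trips unchanged.
#'
#' @param config A [pipeline_config].
#' @param path YAML file path.
#' @return `write_pipeline_config`: `path`, invisibly;
#'   `read_pipeline_config`: a [pipeline_config].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    s <- raw$synthetic
    specs <- lapply(s$module_specs, function(m) {
      planted_module(m$size, m$biotype, m$direction, m$effect_log2,
                     m$loading, m$homogeneity, m$state)
    })
    syn <- synthetic_config(s$n_mrna, s$n_lncrna, s$n_case, s$n_control,
                            specs, s$noise_sd, s$baseline_mean, s$n_datasets,
                            s$shared_gene_fraction, s$seed)
  }
  pipeline_config(input_mode = raw$input_mode,
                  synthetic = if (is.null(syn)) synthetic_config() else syn,
                  datasets = if (is.null(raw$datasets)) list() else raw$datasets,
                  gmt_file = raw$gmt_file,
                  alpha = raw$alpha, fc_threshold = raw$fc_threshold,
                  candidate_powers = raw$candidate_powers,
                  r2_target = raw$r2_target,
                  min_module_size = unlist(raw$min_module_size),
                  homogeneity_threshold = raw$homogeneity_threshold,
                  edge_threshold = unlist(raw$edge_threshold),
                  k_neighbors = raw$k_neighbors,
                  exclude = as.character(unlist(raw$exclude)),
                  out_dir = raw$out_dir, seed = raw$seed)
}

# Subset a differential_result by biotype, preserving class and attributes.
de_subset_biotype <- function(de, biotype) {
  out <- de[de$biotype == biotype, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("alpha", "fc_threshold", "dataset_id", "adjust")) {
    attr(out, a) <- attr(de, a)
  }
  class(out) <- class(de)
  out
}

run_stage <- function(stage, dataset_id, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage=%s dataset=%s error=%s", stage, dataset_id,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed for dataset '%s': %s",
                 stage, dataset_id, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — ingest or simulate, differential
#' expression per dataset, per-state per-biotype network construction and
#' module detection, module direction classification, cross-dataset
#' common-module identification for both directions and biotypes, and
#' guilt-by-association annotation of any common lncRNAs — writing every
#' stage output plus a JSON manifest with parameters and file checksums.
#' Identical configuration and seed produce identical outputs.
#'
#' @param config A [pipeline_config].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`). Key elements: `network_runs` (one row per
#'   dataset x state x biotype), `common` (per biotype/direction summary),
#'   `files` (relative path -> md5).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))

  # --- ingest -------------------------------------------------------------
  datasets <- run_stage("ingest", "-", out_dir, {
    if (config$input_mode == "simulate") {
      lapply(seq_len(config$synthetic$n_datasets),
             function(d) generate_dataset(config$synthetic, d))
    } else {
      lapply(config$datasets, function(ds) {
        read_expression_tsv(ds$matrix, ds$conditions, ds$biotypes,
                            if (is.null(ds$id)) basename(ds$matrix) else ds$id)
      })
    }
  })
  names(datasets) <- vapply(datasets, function(d) d$dataset_id, "")
  collection <- run_stage("ontology", "-", out_dir, {
    if (config$input_mode == "simulate") {
      generate_ontology(config$synthetic)
    } else if (!is.null(config$gmt_file)) read_gmt(config$gmt_file) else NULL
  })

  # --- differential expression --------------------------------------------
  de_results <- lapply(datasets, function(data) {
    run_stage("differential_expression", data$dataset_id, out_dir, {
      de <- compute_de(data, config$alpha, config$fc_threshold)
      write_de_tsv(de, file.path(out_dir, paste0("de_", data$dataset_id, ".tsv")))
      de
    })
  })
  de_summary <- do.call(rbind, lapply(names(de_results), function(ds) {
    do.call(rbind, lapply(c("mRNA", "lncRNA"), function(bt) {
      sub <- de_subset_biotype(de_results[[ds]], bt)
      if (!nrow(sub)) return(NULL)
      cbind(dataset = ds, biotype = bt, de_fraction(sub, nrow(sub)))
    }))
  }))
  utils::write.table(de_summary, file.path(out_dir, "de_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- per-state per-biotype networks and modules -------------------------
  runs <- list()
  partitions <- list()
  summaries <- list()
  for (ds in names(datasets)) {
    for (state in c("case", "control")) {
      for (bt in c("mRNA", "lncRNA")) {
        key <- paste(ds, state, bt, sep = ".")
        res <- run_stage("network", ds, out_dir, {
          de <- de_results[[ds]]
          feats <- de$symbol[de$significant & de$biotype == bt]
          min_size <- config$min_module_size[[bt]]
          if (length(feats) < max(min_size, 3)) {
            part <- structure(list(labels = stats::setNames(integer(0), character(0)),
                                   sizes = integer(0), n_modules = 0L,
                                   min_module_size = as.integer(min_size)),
                              class = "module_partition")
            summ <- summarize_state(part, de, config$homogeneity_threshold,
                                    state = state, dataset_id = ds)
            list(run = data.frame(dataset = ds, state = state, biotype = bt,
                                  n_features = length(feats), power = NA_real_,
                                  scale_free_r2 = NA_real_, n_modules = 0L,
                                  stringsAsFactors = FALSE),
                 partition = part, summary = summ)
          } else {
            corr <- pcc_matrix(datasets[[ds]], feats, state)
            pw <- suppressWarnings(
              select_power(corr, config$candidate_powers, config$r2_target))
            tomat <- tom_matrix(adjacency_matrix(corr, pw$power))
            part <- detect_modules(tomat, min_size)
            summ <- summarize_state(part, de, config$homogeneity_threshold,
                                    state = state, dataset_id = ds)
            edges <- strong_edges(corr, config$edge_threshold[[bt]])
            write_sif(edges, file.path(out_dir, paste0("edges_", key, ".sif")))
            write_edges_tsv(edges, file.path(out_dir, paste0("edges_", key, ".tsv")))
            utils::write.table(
              data.frame(symbol = names(part$labels), module = part$labels,
                         color = module_colors(part$labels)),
              file.path(out_dir, paste0("modules_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(summ$modules,
              file.path(out_dir, paste0("module_summary_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
            list(run = data.frame(dataset = ds, state = state, biotype = bt,
                                  n_features = length(feats), power = pw$power,
                                  scale_free_r2 = pw$r_squared,
                                  n_modules = part$n_modules,
                                  stringsAsFactors = FALSE),
                 partition = part, summary = summ)
          }
        })
        runs[[key]] <- res$run
        partitions[[key]] <- res$partition
        summaries[[key]] <- res$summary
      }
    }
  }
  network_runs <- do.call(rbind, c(runs, list(make.row.names = FALSE)))
  utils::write.table(network_runs, file.path(out_dir, "network_runs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- cross-dataset common modules (sepsis-state networks) ---------------
  common <- list()
  if (length(datasets) >= 2L) {
    for (bt in c("mRNA", "lncRNA")) {
      de_bt <- lapply(de_results, de_subset_biotype, biotype = bt)
      if (!all(vapply(de_bt, nrow, 0L) > 0)) next
      for (direction in c("up", "down")) {
        key <- paste0(bt, "_", direction)
        ov <- overlap_gene_set(de_bt, direction)
        if (!length(ov)) next
        part_bt <- partitions[paste(names(datasets), "case", bt, sep = ".")]
        summ_bt <- summaries[paste(names(datasets), "case", bt, sep = ".")]
        names(part_bt) <- names(summ_bt) <- names(datasets)
        res <- tryCatch(
          find_common_modules(part_bt, summ_bt, ov, direction,
                              exclude = config$exclude),
          error = function(e) NULL)
        if (is.null(res)) next
        common[[key]] <- res
        writeLines(res$common_genes,
                   file.path(out_dir, paste0("common_genes_", key, ".txt")))
        jsonlite::write_json(
          list(direction = res$direction, selections = res$selections,
               excluded = as.list(res$excluded), common_genes = res$common_genes),
          file.path(out_dir, paste0("common_modules_", key, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
  }

  # --- guilt-by-association annotation of common lncRNAs ------------------
  annotations <- list()
  if (!is.null(collection) &&
      (!is.null(common$lncRNA_up) || !is.null(common$lncRNA_down))) {
    lncs <- unique(c(if (!is.null(common$lncRNA_up)) common$lncRNA_up$common_genes,
                     if (!is.null(common$lncRNA_down)) common$lncRNA_down$common_genes))
    ref <- datasets[[setdiff(names(datasets), config$exclude)[1]]]
    lnc_expr <- select_biotype(ref, "lncRNA")
    mrna_expr <- select_biotype(ref, "mRNA")
    for (lnc in lncs) {
      res <- run_stage("lncrna_annotation", ref$dataset_id, out_dir, {
        annotate_lncrna(lnc, lnc_expr, mrna_expr, collection, config$k_neighbors)
      })
      annotations[[lnc]] <- res
      utils::write.table(res, file.path(out_dir, paste0("lncrna_annotation_", lnc, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- manifest -----------------------------------------------------------
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(
    package = "comodhom",
    version = as.character(utils::packageVersion("comodhom")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = config_to_list(config),
    n_datasets = length(datasets),
    de_tables = length(de_results),
    network_runs = network_runs,
    n_common_results = length(common),
    common = lapply(common, function(x) {
      list(direction = x$direction, n_datasets = x$n_datasets,
           n_common_genes = length(x$common_genes),
           common_genes = x$common_genes, excluded = as.list(x$excluded))
    }),
    n_lncrna_annotations = length(annotations),
    files = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
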