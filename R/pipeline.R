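pipeline_defaults <- list(
  threshold = "auto", grid_step = 0.01, node_policy = "nonisolated",
  condition_field = "braf_status", condition_a = "wt", condition_b = "V600E",
  missing_policy = "drop_gene", log2_transform = FALSE, zscore = TRUE,
  normalize_sample_ids = FALSE, seed = 1, log_level = "info")

#' Validate a pipeline configuration
#'
#' Reads a flat key-value YAML file (or takes a named list), fills in
#' defaults, and collects every validation error before reporting.
#'
#' Recognized keys: `expression`, `annotations`, `output_dir` (required);
#' `panel`, `signature` (optional gene-list paths); `threshold` (`"auto"` or
#' a number in (0,1]); `grid_step`; `node_policy`
#' (`nonisolated`/`strict`); `condition_field`, `condition_a`,
#' `condition_b`; `missing_policy` (`drop_gene`/`zero_fill`);
#' `log2_transform`, `zscore`, `normalize_sample_ids` (truncate sample ids
#' to the first 15 characters, the TCGA barcode prefix); `seed`;
#' `log_level`.
#'
#' @param config Path to a YAML config or a named list.
#' @return The validated config (a named list) or an error listing every
#'   problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_dcornet("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults, config)
  errors <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)

  for (key in c("expression", "annotations", "output_dir")) {
    need(!is.null(config[[key]]), paste0("missing required key: ", key))
  }
  for (key in c("expression", "annotations", "panel", "signature")) {
    if (!is.null(cfg[[key]])) {
      need(file.exists(cfg[[key]]), paste0(key, " file not found: ", cfg[[key]]))
    }
  }
  if (!identical(cfg$threshold, "auto")) {
    need(is.numeric(cfg$threshold) && cfg$threshold > 0 && cfg$threshold <= 1,
         "threshold must be 'auto' or a number in (0, 1]")
  }
  need(is.numeric(cfg$grid_step) && cfg$grid_step > 0 && cfg$grid_step < 1,
       "grid_step must be in (0, 1)")
  need(cfg$node_policy %in% c("nonisolated", "strict"),
       "node_policy must be 'nonisolated' or 'strict'")
  need(cfg$missing_policy %in% c("drop_gene", "zero_fill"),
       "missing_policy must be 'drop_gene' or 'zero_fill'")
  need(is_count(cfg$seed), "seed must be an integer")
  need(is.character(cfg$condition_a) || is.character(cfg$condition_b) ||
         TRUE, "")  # condition values coerced below
  cfg$condition_a <- as.character(cfg$condition_a)
  cfg$condition_b <- as.character(cfg$condition_b)
  need(nzchar(cfg$condition_a) && nzchar(cfg$condition_b) &&
         cfg$condition_a != cfg$condition_b,
       "condition_a and condition_b must be two distinct values")
  if (length(errors) > 0) {
    stop_dcornet("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  cfg
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full differential-network pipeline from a configuration
#'
#' Executes the six analysis stages — input loading, optional signature
#' stratification, per-condition Spearman correlation, network
#' reconstruction, topology profiling, and the merged-network comparison —
#' and writes every result plus a run manifest (input hashes, parameters,
#' package version) into `output_dir`. Outputs are deterministic: a rerun
#' with an identical config and inputs produces byte-identical files.
#'
#' @param config Path to a YAML config or a named list
#'   (see [validate_config()]).
#' @return Invisibly, the fitted [dcn] object (with the manifest in
#'   `$manifest`). A stage failure aborts with the stage name and cause.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  stages <- character(0)
  stage <- function(name, code) {
    pipe_log(cfg, "stage ", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      stop_dcornet("pipeline stage ", dQuote(name), " failed: ",
                   conditionMessage(e))
    })
    pipe_log(cfg, "stage ", name, " done (",
             sprintf("%.2f", proc.time()[["elapsed"]] - t0), "s)")
    stages <<- c(stages, name)
    res
  }

  loaded <- stage("load", {
    expr <- read_expression_tsv(cfg$expression, missing_policy = cfg$missing_policy,
                                log2_transform = cfg$log2_transform)
    if (isTRUE(cfg$normalize_sample_ids)) {
      colnames(expr) <- substr(colnames(expr), 1, 15)
    }
    ann <- read_annotations_tsv(cfg$annotations)
    if (isTRUE(cfg$normalize_sample_ids)) {
      ann$sample_id <- substr(ann$sample_id, 1, 15)
    }
    panel <- if (!is.null(cfg$panel)) read_gene_set(cfg$panel, "panel")
    signature <- if (!is.null(cfg$signature)) read_gene_set(cfg$signature, "signature")
    for (v in c(cfg$condition_a, cfg$condition_b)) {
      if (!any(ann[[cfg$condition_field]] == v & ann$sample_id %in% colnames(expr))) {
        stop_dcornet("condition value ", dQuote(v), " matches 0 usable samples")
      }
    }
    list(expr = expr, ann = ann, panel = panel, signature = signature)
  })

  strat <- NULL
  if (!is.null(loaded$signature)) {
    strat <- stage("stratify", {
      s <- ward_cluster_samples(loaded$expr, loaded$signature, zscore = cfg$zscore)
      write_tsv(data.frame(sample_id = names(s$labels), group = s$labels),
                out("stratification.tsv"))
      mrg <- s$sample_hclust$merge
      write_tsv(data.frame(merge1 = mrg[, 1], merge2 = mrg[, 2],
                           height = s$sample_hclust$height),
                out("stratification_linkage.tsv"))
      export_heatmap_matrix(loaded$expr, s, out("heatmap_matrix.tsv"))
      s
    })
  }

  fit <- stage("correlate_network_topology", {
    dcn(loaded$expr, loaded$ann, panel = loaded$panel, signature = NULL,
        condition = cfg$condition_field,
        conditions = c(cfg$condition_a, cfg$condition_b),
        threshold = if (identical(cfg$threshold, "auto")) NULL else cfg$threshold,
        grid_step = cfg$grid_step, node_policy = cfg$node_policy)
  })
  fit$stratification <- strat

  stage("write_condition_outputs", {
    for (i in 1:2) {
      cond <- fit$conditions[i]
      cp <- fit$correlations[[i]]
      write_tsv(data.frame(gene = rownames(cp$rho),
                           as.data.frame(cp$rho), check.names = FALSE),
                out(paste0("correlation_", cond, ".tsv")))
      nt <- fit$networks[[i]]
      write_network(nt, out(paste0("network_", cond, ".graphml")), "graphml")
      write_network(nt, out(paste0("network_", cond, ".sif")), "sif")
      write_network(nt, out(paste0("network_", cond, ".edges.tsv")), "edge_tsv")
      rep <- fit$topology[[i]]
      write_json_report(c(rep$global, list(fragmented = rep$fragmented,
                                           threshold_used = nt$threshold)),
                        out(paste0("topology_", cond, ".json")))
      write_tsv(rep$nodes, out(paste0("topology_nodes_", cond, ".tsv")))
      write_tsv(rep$edges, out(paste0("topology_edges_", cond, ".tsv")))
    }
  })

  stage("diffnet", {
    write_tsv(fit$merged$nodes, out("merged_nodes.tsv"))
    g <- fit$merged$graph
    nd <- fit$merged$nodes
    igraph::V(g)$dn <- nd$rewiring_dn[match(igraph::V(g)$name, nd$gene)]
    igraph::write_graph(g, out("merged.graphml"), format = "graphml")
    write_tsv(betweenness_variation(fit$merged), out("betweenness_variation.tsv"))
    write_tsv(fit$comparison$global, out("comparison_global.tsv"))
    write_tsv(fit$comparison$edges, out("edge_rank_shifts.tsv"))
    write_json_report(
      list(conditions = as.list(stats::setNames(fit$conditions, c("A", "B"))),
           thresholds = lapply(fit$networks, `[[`, "threshold"),
           edge_counts = as.list(fit$merged$edge_counts),
           global = stats::setNames(
             lapply(seq_len(nrow(fit$comparison$global)), function(r)
               list(A = fit$comparison$global$A[r],
                    B = fit$comparison$global$B[r])),
             fit$comparison$global$metric)),
      out("comparison.json"))
  })

  manifest <- stage("manifest", {
    inputs <- Filter(Negate(is.null),
                     cfg[c("expression", "annotations", "panel", "signature")])
    m <- list(
      package = "dcornet",
      version = as.character(utils::packageVersion("dcornet")),
      parameters = cfg[setdiff(names(cfg), c("log_level", "output_dir"))],
      input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
      stages = c(stages, "manifest"))
    write_json_report(m, out("manifest.json"))
    m
  })

  fit$manifest <- manifest
  invisible(fit)
}

#' Write a simulated cohort to disk
#'
#' Convenience wrapper around [generate_cohort()] that writes the expression
#' TSV, annotation TSV and ground-truth JSON the pipeline and its tests
#' consume.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_per_condition,r_within,n_rewired,shift,noise_sd,frac_high
#'   Design parameters; defaults follow [default_block_design()] and
#'   [generate_cohort()].
#' @return Invisibly, the cohort list with `paths` added.
#' @export
simulate_cohort_files <- function(out_dir, seed, n_per_condition = 300,
                                  r_within = 0.7, n_rewired = 4, shift = 2,
                                  noise_sd = 0.3, frac_high = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- default_block_design(r_within = r_within, n_rewired = n_rewired)
  cohort <- generate_cohort(design$blocks_A, design$blocks_B,
                            n_per_condition = n_per_condition,
                            signature_genes = design$signature_genes,
                            shift = shift, frac_high = frac_high,
                            noise_sd = noise_sd, seed = seed)
  paths <- list(expression = file.path(out_dir, "expression.tsv"),
                annotations = file.path(out_dir, "annotations.tsv"),
                truth = file.path(out_dir, "truth.json"),
                signature = file.path(out_dir, "signature_genes.txt"))
  write_expression_tsv(cohort$expr, paths$expression)
  write_tsv(cohort$annotations, paths$annotations)
  writeLines(design$signature_genes, paths$signature)
  tr <- cohort$truth
  write_json_report(
    list(phenotype_labels = as.list(tr$phenotype_labels),
         condition_labels = as.list(tr$condition_labels),
         planted_edges_A = tr$planted_edges_A,
         planted_edges_B = tr$planted_edges_B,
         rewired_genes = as.list(tr$rewired_genes)),
    paths$truth)
  cohort$paths <- paths
  invisible(cohort)
}
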