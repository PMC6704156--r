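#' Read a genes-by-samples expression matrix from tab-separated text
#'
#' Parses the standard layout used for TCGA Firehose level-3 mRNA-seq tables:
#' first column gene identifiers, header row of sample identifiers, one gene
#' per row. Identifiers of the form `"SYMBOL|entrez"` are reduced to the
#' symbol part. Duplicate gene symbols are collapsed by keeping the row with
#' the highest mean expression (a message reports which rows were dropped).
#'
#' @param path Path to a tab-separated file.
#' @param missing_policy How to handle blank/NA expression cells:
#'   `"drop_gene"` removes any gene row containing a missing value,
#'   `"zero_fill"` replaces missing values with 0.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the values after
#'   missing-value handling. Rank-based (Spearman) analyses are unaffected by
#'   this monotone transform; it matters only for Euclidean-distance
#'   clustering and heatmap export.
#' @return A numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns (colnames = sample identifiers).
#' @export
read_expression_tsv <- function(path,
                                missing_policy = c("drop_gene", "zero_fill"),
                                log2_transform = FALSE) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop_dcornet("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_dcornet("expression file is empty: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    stop_dcornet("malformed header (line 1): expected at least one sample column, got ",
                 length(header), " field(s)")
  }
  sample_ids <- trimws(header[-1])
  if (anyDuplicated(sample_ids)) {
    stop_dcornet("malformed header (line 1): duplicated sample identifiers: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(lines) < 2) stop_dcornet("expression file has a header but no gene rows: ", path)

  # sentinel keeps trailing empty fields that strsplit would drop
  rows <- lapply(strsplit(paste0(lines[-1], "\tEND"), "\t", fixed = TRUE),
                 function(r) r[-length(r)])
  nfields <- lengths(rows)
  bad <- which(nfields != length(header))
  if (length(bad) > 0) {
    stop_dcornet("parse error at line ", bad[1] + 1, ": expected ",
                 length(header), " fields, found ", nfields[bad[1]])
  }
  genes <- vapply(rows, function(r) sub("\\|.*$", "", trimws(r[1])), character(1))
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    cells <- trimws(rows[[i]][-1])
    missing <- cells == "" | toupper(cells) %in% c("NA", "NAN", "NULL")
    num <- suppressWarnings(as.numeric(cells))
    bad_cell <- which(!missing & is.na(num))
    if (length(bad_cell) > 0) {
      stop_dcornet("parse error at line ", i + 1, ", column ", bad_cell[1] + 1,
                   ": non-numeric value ", dQuote(cells[bad_cell[1]]))
    }
    num[missing] <- NA_real_
    vals[i, ] <- num
  }

  if (missing_policy == "zero_fill") {
    vals[is.na(vals)] <- 0
  } else {
    keep <- rowSums(is.na(vals)) == 0
    if (!all(keep)) {
      message("read_expression_tsv: dropped ", sum(!keep),
              " gene(s) with missing values: ",
              paste(utils::head(genes[!keep], 10), collapse = ", "),
              if (sum(!keep) > 10) ", ..." else "")
    }
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (nrow(vals) == 0) stop_dcornet("no gene rows left after missing-value handling")

  # collapse duplicate symbols: keep the highest-mean row
  key <- canon_symbol(genes)
  if (anyDuplicated(key)) {
    means <- rowMeans(vals)
    ord <- order(means, decreasing = TRUE)
    keep_idx <- ord[!duplicated(key[ord])]
    keep_idx <- sort(keep_idx)
    dropped <- setdiff(seq_along(key), keep_idx)
    message("read_expression_tsv: collapsed ", length(dropped),
            " duplicate gene row(s) by keeping the highest-mean row: ",
            paste(unique(genes[dropped]), collapse = ", "))
    vals <- vals[keep_idx, , drop = FALSE]
    genes <- genes[keep_idx]
  }

  if (log2_transform) vals <- log2(vals + 1)
  dimnames(vals) <- list(genes, sample_ids)
  vals
}

#' Read a gene set from a plain-text list
#'
#' One symbol per line; lines starting with `#` and blank lines are ignored.
#' Duplicates (case-insensitive) are removed with a warning; order is
#' preserved.
#'
#' @param path Path to the list file.
#' @param name Label for the set (default: file name without extension).
#' @return Character vector of symbols with attribute `set_name`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop_dcornet("gene-set file not found: ", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_dcornet("gene set ", dQuote(name), " is empty after parsing")
  dup <- duplicated(canon_symbol(lines))
  if (any(dup)) {
    warning("gene set ", dQuote(name), ": removed duplicate symbol(s): ",
            paste(unique(lines[dup]), collapse = ", "), call. = FALSE)
    lines <- lines[!dup]
  }
  structure(lines, set_name = name)
}

#' Read a sample annotation table
#'
#' Requires tab-separated columns `sample_id`, `braf_status`, `sample_type`.
#' BRAF status strings other than `V600E` / `wt` (case-insensitive) are mapped
#' to `unknown` with a warning; sample types other than metastatic/primary map
#' to `other`.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `sample_id`, `braf_status`,
#'   `sample_type`.
#' @export
read_annotations_tsv <- function(path) {
  if (!file.exists(path)) stop_dcornet("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "braf_status", "sample_type")
  absent <- setdiff(required, names(df))
  if (length(absent) > 0) {
    stop_dcornet("annotation table is missing required column(s): ",
                 paste(absent, collapse = ", "))
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id)) {
    stop_dcornet("annotation table has duplicated sample_id: ",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  raw_status <- trimws(as.character(df$braf_status))
  status <- rep("unknown", length(raw_status))
  status[toupper(raw_status) == "V600E"] <- "V600E"
  status[tolower(raw_status) %in% c("wt", "wild-type", "wildtype")] <- "wt"
  odd <- status == "unknown" & !(tolower(raw_status) %in% c("unknown", "na", ""))
  if (any(odd)) {
    warning("mapped unrecognized braf_status value(s) to 'unknown': ",
            paste(unique(raw_status[odd]), collapse = ", "), call. = FALSE)
  }
  raw_type <- tolower(trimws(as.character(df$sample_type)))
  stype <- rep("other", length(raw_type))
  stype[raw_type == "metastatic"] <- "metastatic"
  stype[raw_type == "primary"] <- "primary"
  data.frame(sample_id = df$sample_id, braf_status = status,
             sample_type = stype, stringsAsFactors = FALSE)
}

#' Subset an expression matrix by genes and/or samples
#'
#' Gene symbols are matched case-insensitively; the order of the request is
#' preserved. Requested identifiers that are absent from the matrix are
#' reported via a message and returned in the `absent_genes` /
#' `absent_samples` attributes of the result.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Character vector of symbols, or `NULL` to keep all genes.
#' @param samples Character vector of sample identifiers, or `NULL`.
#' @return The subset matrix (attributes `absent_genes`, `absent_samples`).
#' @export
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  stopifnot(is.matrix(expr))
  absent_g <- character(0)
  absent_s <- character(0)
  if (!is.null(genes)) {
    idx <- match_symbols(genes, rownames(expr))
    absent_g <- genes[is.na(idx)]
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) stop_dcornet("no requested genes found in the matrix")
    expr <- expr[idx, , drop = FALSE]
  }
  if (!is.null(samples)) {
    idx <- match(samples, colnames(expr))
    absent_s <- samples[is.na(idx)]
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) stop_dcornet("no requested samples found in the matrix")
    expr <- expr[, idx, drop = FALSE]
  }
  if (length(absent_g) > 0 || length(absent_s) > 0) {
    message("subset_expression: absent identifiers ignored: ",
            paste(c(absent_g, absent_s), collapse = ", "))
  }
  attr(expr, "absent_genes") <- absent_g
  attr(expr, "absent_samples") <- absent_s
  expr
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_tsv()]; full-precision values.
#'
#' @param expr Expression matrix.
#' @param path Output path.
#' @param id_column Name for the gene-identifier column.
#' @export
write_expression_tsv <- function(expr, path, id_column = "gene") {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a correlation network to disk
#'
#' @param network A `cor_network` object (see [build_network()]).
#' @param path Output path.
#' @param format `"graphml"` (node/edge attributes preserved), `"sif"`
#'   (Cytoscape simple-interaction format, relation `cc`), or `"edge_tsv"`
#'   (columns `gene_a`, `gene_b`, `rho`, `abs_rho`).
#' @export
write_network <- function(network, path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "cor_network"))
  g <- network$graph
  if (format == "graphml") {
    igraph::graph_attr(g, "threshold_used") <- network$threshold
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    ed <- network_edges(network)
    lines <- if (nrow(ed) > 0) paste(ed$gene_a, "cc", ed$gene_b, sep = "\t") else character(0)
    writeLines(lines, path)
  } else {
    ed <- network_edges(network)
    utils::write.table(format(ed, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML correlation network written by [write_network()]
#'
#' @param path GraphML file path.
#' @return A `cor_network` object.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  thr <- igraph::graph_attr(g, "threshold_used")
  # graphml ids can shadow names; keep the name attribute authoritative
  new_cor_network(g, threshold = thr %||% NA_real_,
                  node_policy = "as_read", n_samples = NA_integer_)
}

#' Edge table of a correlation network
#'
#' @param network A `cor_network`.
#' @return data.frame with columns `gene_a`, `gene_b`, `rho`, `abs_rho`.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "cor_network"))
  g <- network$graph
  if (igraph::ecount(g) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      rho = numeric(0), abs_rho = numeric(0)))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(gene_a = el[, 1], gene_b = el[, 2],
             rho = igraph::E(g)$rho, abs_rho = abs(igraph::E(g)$rho),
             stringsAsFactors = FALSE)
}
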