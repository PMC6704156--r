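#' Stratify samples into signature-high and signature-low groups
#'
#' Reproduces the standard immune-signature stratification of a tumour
#' cohort: samples are clustered by Ward linkage (Lance-Williams `ward.D2`
#' update) on Euclidean distances between their profiles over the signature
#' genes, the tree is cut into `k` clusters, and, when `k = 2`, the cluster
#' with the greater mean signature expression is labelled `high`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param signature Character vector of signature gene symbols.
#' @param k Number of clusters to cut (default 2).
#' @param zscore Z-score each signature gene across samples before computing
#'   distances (default `TRUE`, the usual convention for signature heatmaps);
#'   constant genes are excluded with a warning either way.
#' @return A `cluster_assignment`: list with `labels` (named character,
#'   `"high"`/`"low"` for `k = 2`, `"cluster<j>"` otherwise),
#'   `sample_hclust` (the `hclust` tree), `signature_used`, `k`.
#' @export
ward_cluster_samples <- function(expr, signature, k = 2, zscore = TRUE) {
  stopifnot(is.matrix(expr), is_count(k), k >= 2)
  idx <- match_symbols(signature, rownames(expr))
  idx <- idx[!is.na(idx)]
  sub <- expr[idx, , drop = FALSE]
  if (nrow(sub) > 0) {
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) {
      warning("excluding constant signature gene(s): ",
              paste(rownames(sub)[sds == 0], collapse = ", "), call. = FALSE)
      sub <- sub[sds > 0, , drop = FALSE]
    }
  }
  if (nrow(sub) < 2) stop_dcornet("fewer than 2 usable signature genes in the matrix")
  if (ncol(sub) < k) stop_dcornet("need at least k samples")
  work <- if (zscore) t(scale(t(sub))) else sub
  hc <- stats::hclust(stats::dist(t(work)), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)

  if (k == 2) {
    means <- tapply(colMeans(sub), grp, mean)
    if (means[["1"]] != means[["2"]]) {
      high_id <- as.integer(names(which.max(means)))
    } else {
      # deterministic tie-break: larger cluster, then lexicographic first sample
      sizes <- table(grp)
      if (sizes[["1"]] != sizes[["2"]]) {
        high_id <- as.integer(names(which.max(sizes)))
      } else {
        firsts <- tapply(colnames(sub), grp, function(s) sort(s)[1])
        high_id <- as.integer(names(firsts)[order(firsts)[1]])
      }
    }
    labels <- ifelse(grp == high_id, "high", "low")
  } else {
    labels <- paste0("cluster", grp)
  }
  structure(list(labels = stats::setNames(labels, colnames(sub)),
                 sample_hclust = hc,
                 signature_used = rownames(sub), k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Sample stratification (Ward / Euclidean on", length(x$signature_used),
      "signature genes)\n")
  print(table(x$labels))
  invisible(x)
}

#' Order genes by Ward clustering on correlation distance
#'
#' Clusters genes with Ward linkage on the dissimilarity `d = 1 - r`, where
#' `r` is the gene-gene correlation across samples, and returns the
#' dendrogram leaf order (the row order used for signature heatmaps).
#' Zero-variance genes are excluded with a warning.
#'
#' @param expr Expression matrix.
#' @param genes Symbols to cluster (default: all rows).
#' @param method Correlation flavour for the distance, `"pearson"` (default)
#'   or `"spearman"`.
#' @return Character vector of symbols in leaf order, with the `hclust` tree
#'   in attribute `hclust`.
#' @export
ward_cluster_genes <- function(expr, genes = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr))
  if (!is.null(genes)) {
    idx <- match_symbols(genes, rownames(expr))
    expr <- expr[idx[!is.na(idx)], , drop = FALSE]
  }
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant gene(s) from gene clustering: ",
            paste(rownames(expr)[sds == 0], collapse = ", "), call. = FALSE)
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop_dcornet("fewer than 2 usable genes")
  r <- stats::cor(t(expr), method = method)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
  structure(rownames(expr)[hc$order], hclust = hc)
}

#' Export the reordered, z-scored heatmap matrix for a stratified cohort
#'
#' Writes a TSV whose first row annotates each sample with its high/low
#' group, with samples in dendrogram order and genes in correlation-distance
#' leaf order, values z-scored per gene (constant rows become 0 with a
#' warning). This is the numeric content of a signature heatmap; rendering
#' is left to the caller.
#'
#' @param expr Expression matrix the assignment was derived from.
#' @param assignment A `cluster_assignment` from [ward_cluster_samples()].
#' @param path Output TSV path.
#' @param genes Genes to include (default: the signature used).
#' @return Invisibly, the written matrix.
#' @export
export_heatmap_matrix <- function(expr, assignment, path, genes = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  genes <- genes %||% assignment$signature_used
  idx <- match_symbols(genes, rownames(expr))
  sub <- expr[idx[!is.na(idx)], , drop = FALSE]
  sample_order <- assignment$sample_hclust$labels[assignment$sample_hclust$order]
  sub <- sub[, sample_order, drop = FALSE]
  gene_order <- tryCatch(as.character(ward_cluster_genes(sub)),
                         error = function(e) rownames(sub))
  # constant genes fall out of the correlation ordering; keep them at the end
  gene_order <- c(gene_order, setdiff(rownames(sub), gene_order))
  sub <- sub[match_symbols(gene_order, rownames(sub)), , drop = FALSE]

  z <- t(apply(sub, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  if (any(apply(sub, 1, stats::sd) == 0)) {
    warning("constant gene row(s) z-scored to 0", call. = FALSE)
  }
  dimnames(z) <- dimnames(sub)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("group", assignment$labels[colnames(z)]), collapse = "\t"), con)
  df <- data.frame(gene = rownames(z),
                   format(z, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(z)
}
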