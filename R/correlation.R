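#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), computed on
#' pairwise-complete observations. Errors on constant input, where the
#' correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop_dcornet("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_dcornet("need at least 3 complete observation pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_dcornet("Spearman correlation undefined for constant input")
  }
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation matrix over a gene panel
#'
#' All pairwise Spearman correlations among the panel genes, on
#' pairwise-complete observations. Constant genes are dropped with a warning
#' and listed in the result.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Panel symbols (default: all rows).
#' @param use Observation policy passed to [stats::cor()]:
#'   `"pairwise.complete.obs"` (default) or `"complete.obs"` (listwise).
#' @return A `cor_panel` object: list with `rho` (symmetric matrix, unit
#'   diagonal), `n_samples`, `dropped` (constant genes removed).
#' @export
correlation_matrix <- function(expr, genes = NULL,
                               use = c("pairwise.complete.obs", "complete.obs")) {
  use <- match.arg(use)
  stopifnot(is.matrix(expr))
  if (!is.null(genes)) expr <- subset_expression(expr, genes = as.character(genes))
  sds <- apply(expr, 1, stats::sd, na.rm = TRUE)
  dropped <- rownames(expr)[is.na(sds) | sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant gene(s) from correlation matrix: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    expr <- expr[!(rownames(expr) %in% dropped), , drop = FALSE]
  }
  if (nrow(expr) < 2) stop_dcornet("fewer than 2 genes with non-zero variance")
  rho <- stats::cor(t(expr), method = "spearman", use = use)
  structure(list(rho = rho, genes = rownames(rho),
                 n_samples = ncol(expr), dropped = dropped),
            class = "cor_panel")
}

#' @export
print.cor_panel <- function(x, ...) {
  cat("Spearman correlation panel:", length(x$genes), "genes,",
      x$n_samples, "samples\n")
  off <- x$rho[upper.tri(x$rho)]
  if (length(off)) {
    cat(sprintf("  |rho| range %.3f - %.3f, median %.3f\n",
                min(abs(off)), max(abs(off)), stats::median(abs(off))))
  }
  invisible(x)
}

#' Rectangular Spearman correlation between two gene panels
#'
#' One rho per (row gene, column gene) pair, e.g. immune-signature genes
#' against kynurenine-pathway genes. Constant genes are dropped as in
#' [correlation_matrix()].
#'
#' @param expr Expression matrix.
#' @param rows,cols Symbols for the row and column panels.
#' @return Numeric matrix of Spearman correlations, rows x cols.
#' @export
cross_correlation <- function(expr, rows, cols) {
  stopifnot(is.matrix(expr))
  pick <- function(genes) {
    m <- subset_expression(expr, genes = as.character(genes))
    sds <- apply(m, 1, stats::sd, na.rm = TRUE)
    if (any(sds == 0, na.rm = TRUE)) {
      warning("dropping constant gene(s): ",
              paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
      m <- m[!is.na(sds) & sds > 0, , drop = FALSE]
    }
    if (nrow(m) < 1) stop_dcornet("panel empty after variance filtering")
    m
  }
  a <- pick(rows); b <- pick(cols)
  stats::cor(t(a), t(b), method = "spearman", use = "pairwise.complete.obs")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change `2^-((Ct_target,case - Ct_ref,case) - (Ct_target,ctrl -
#' Ct_ref,ctrl))` for qPCR cycle-threshold readouts normalized to an internal
#' reference gene.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene, case.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene, control.
#' @return Fold change relative to control.
#' @export
relative_expression <- function(ct_target_case, ct_ref_case,
                                ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals))) stop_dcornet("Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
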