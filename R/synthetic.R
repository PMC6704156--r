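#' Specify a block of co-expressed genes
#'
#' A block is a set of genes sharing a common population (latent Pearson)
#' correlation `r_within`; genes in different blocks share `r_between`
#' (default 0). Blocks define the ground-truth co-expression structure of
#' simulated cohorts.
#'
#' @param block_id Label for the block.
#' @param genes Character vector of member symbols (>= 2, unique).
#' @param r_within Population correlation among members, in `[0, 1)`.
#' @param r_between Background correlation to all other genes (default 0).
#' @return A `block_spec` object.
#' @export
block_spec <- function(block_id, genes, r_within, r_between = 0) {
  stopifnot(is.character(genes), length(genes) >= 2, !anyDuplicated(genes))
  if (!is.numeric(r_within) || r_within < 0 || r_within >= 1) {
    stop_dcornet("block ", block_id, ": r_within must be in [0, 1)")
  }
  if (r_between >= r_within) {
    stop_dcornet("block ", block_id, ": r_between must be smaller than r_within")
  }
  structure(list(block_id = as.character(block_id), genes = genes,
                 r_within = r_within, r_between = r_between),
            class = "block_spec")
}

# Latent correlation matrix implied by a list of block specs over `genes`.
block_sigma <- function(blocks, genes) {
  p <- length(genes)
  sigma <- diag(p)
  dimnames(sigma) <- list(genes, genes)
  for (b in blocks) {
    idx <- match(b$genes, genes)
    if (anyNA(idx)) stop_dcornet("block ", b$block_id, " names genes absent from the universe")
    if (b$r_between != 0) {
      sigma[idx, -idx] <- b$r_between
      sigma[-idx, idx] <- b$r_between
    }
    sigma[idx, idx] <- b$r_within
    diag(sigma)[idx] <- 1
  }
  # membership must be disjoint
  members <- unlist(lapply(blocks, `[[`, "genes"))
  if (anyDuplicated(members)) {
    stop_dcornet("blocks are not disjoint: ",
                 paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  for (b in blocks) {
    idx <- match(b$genes, genes)
    ev <- eigen(sigma[idx, idx], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop_dcornet("block ", b$block_id, " implies a non-positive-semidefinite correlation matrix")
    }
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    culprits <- vapply(blocks, function(b) b$r_between != 0, logical(1))
    stop_dcornet("block design implies a non-positive-semidefinite correlation ",
                 "matrix (check r_between of block(s) ",
                 paste(vapply(blocks[culprits], `[[`, character(1), "block_id"),
                       collapse = ", "), ")")
  }
  sigma
}

#' Population Spearman correlation of a bivariate Gaussian
#'
#' For a bivariate normal pair with Pearson correlation `r`, the population
#' Spearman rank correlation is `(6 / pi) * asin(r / 2)`. Used as the
#' closed-form ground truth for the Gaussian-copula simulator.
#'
#' @param r_pearson Pearson correlation(s) in `[-1, 1]`.
#' @return Population Spearman correlation(s).
#' @export
population_spearman <- function(r_pearson) {
  if (any(!is.finite(r_pearson)) || any(abs(r_pearson) > 1)) {
    stop_dcornet("r_pearson must be in [-1, 1]")
  }
  (6 / pi) * asin(r_pearson / 2)
}

#' Default two-condition block design with planted rewiring
#'
#' Thirty genes `G01..G30`: three blocks of eight plus six singletons in
#' condition A; in condition B, `n_rewired` genes of block 1 move into a new
#' block of their own, rewiring both the moved genes and the block-1 genes
#' they leave behind.
#'
#' @param r_within Within-block latent Pearson correlation (default 0.7).
#' @param n_rewired How many block-1 genes move to a new block in condition B
#'   (default 4; between 2 and 6).
#' @return List with `blocks_A`, `blocks_B`, `genes`, `signature_genes`
#'   (the six singletons) and `rewired_genes` (all genes whose planted edge
#'   set differs between conditions: moved genes plus the block-1 remainder).
#' @export
default_block_design <- function(r_within = 0.7, n_rewired = 4) {
  stopifnot(is_count(n_rewired), n_rewired >= 2, n_rewired <= 6)
  genes <- sprintf("G%02d", 1:30)
  b1 <- genes[1:8]; b2 <- genes[9:16]; b3 <- genes[17:24]
  blocks_A <- list(block_spec("B1", b1, r_within),
                   block_spec("B2", b2, r_within),
                   block_spec("B3", b3, r_within))
  moved <- b1[seq_len(n_rewired)]
  stay <- setdiff(b1, moved)
  blocks_B <- list(block_spec("B1", stay, r_within),
                   block_spec("B2", b2, r_within),
                   block_spec("B3", b3, r_within),
                   block_spec("B4", moved, r_within))
  list(blocks_A = blocks_A, blocks_B = blocks_B, genes = genes,
       signature_genes = genes[25:30], rewired_genes = b1)
}

# Unordered within-block gene pairs for a block list (the planted edges).
planted_edges <- function(blocks) {
  pairs <- do.call(rbind, lapply(blocks, function(b) {
    g <- sort(b$genes)
    if (length(g) < 2) return(NULL)
    cmb <- utils::combn(g, 2)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(gene_a = character(0), gene_b = character(0))
  }
  pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
}

pair_keys <- function(df) paste(df$gene_a, df$gene_b, sep = "|")

#' Simulate a two-condition expression cohort with known structure
#'
#' Per condition, `n_per_condition` samples are drawn from a zero-mean
#' multivariate Gaussian whose correlation matrix is implied by the block
#' specs, plus independent measurement noise of standard deviation
#' `noise_sd`. A fraction `frac_high` of samples in each condition receives a
#' `+shift` offset on every signature gene (phenotype `high`). Condition A is
#' recorded as BRAF `wt` and condition B as `V600E` so the cohort drops
#' straight into the pipeline. With `skew = TRUE` values are mapped through
#' `exp()` (log-normal marginals, mimicking skewed RSEM abundances); the
#' monotone map leaves every rank-based ground truth untouched.
#'
#' @param blocks_A,blocks_B Lists of [block_spec()] for the two conditions.
#' @param n_per_condition Samples per condition (>= 4).
#' @param signature_genes Symbols receiving the phenotype shift.
#' @param shift Mean shift, in latent (unit-variance) expression SD units.
#' @param frac_high Fraction of samples per condition in the high phenotype.
#' @param noise_sd Independent noise SD added to every gene.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param genes Gene universe; defaults to the union of block members and
#'   signature genes (extra genes are independent singletons).
#' @param skew Map expression through `exp()` (default `FALSE`).
#' @return List with `expr` (genes x samples matrix), `annotations`
#'   (data.frame as from [read_annotations_tsv()]), and `truth` (list:
#'   `phenotype_labels`, `condition_labels`, `planted_edges_A`,
#'   `planted_edges_B`, `rewired_genes`, `population_spearman_within` —
#'   the noise-attenuated within-block Spearman correlation).
#' @export
generate_cohort <- function(blocks_A, blocks_B = blocks_A,
                            n_per_condition = 300,
                            signature_genes = character(0),
                            shift = 2, frac_high = 0.5, noise_sd = 0.3,
                            seed, genes = NULL, skew = FALSE) {
  stopifnot(is_count(n_per_condition), n_per_condition >= 4)
  if (!(frac_high > 0 && frac_high < 1)) stop_dcornet("frac_high must be in (0, 1)")
  if (missing(seed) || !is_count(seed)) stop_dcornet("an integer seed is required")
  genes <- genes %||% unique(c(unlist(lapply(blocks_A, `[[`, "genes")),
                               unlist(lapply(blocks_B, `[[`, "genes")),
                               signature_genes))
  sig_idx <- match_symbols(signature_genes, genes)
  if (anyNA(sig_idx)) stop_dcornet("signature genes absent from gene universe")
  sigma_A <- block_sigma(blocks_A, genes)
  sigma_B <- block_sigma(blocks_B, genes)
  p <- length(genes)
  n <- n_per_condition

  draw_condition <- function(sigma, sample_ids) {
    z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
    z <- z + matrix(rnorm(n * p, sd = noise_sd), n, p)
    n_high <- max(1, min(n - 1, round(frac_high * n)))
    high <- sort(sample.int(n, n_high))
    z[high, sig_idx] <- z[high, sig_idx] + shift
    phen <- rep("low", n); phen[high] <- "high"
    x <- t(z)
    if (skew) x <- exp(x)
    dimnames(x) <- list(genes, sample_ids)
    list(x = x, phen = stats::setNames(phen, sample_ids))
  }

  res <- with_seed(seed, {
    a <- draw_condition(sigma_A, sprintf("A%04d", seq_len(n)))
    b <- draw_condition(sigma_B, sprintf("B%04d", seq_len(n)))
    list(a = a, b = b)
  })

  expr <- cbind(res$a$x, res$b$x)
  annotations <- data.frame(
    sample_id = colnames(expr),
    braf_status = rep(c("wt", "V600E"), each = n),
    sample_type = "metastatic",
    stringsAsFactors = FALSE)

  pe_A <- planted_edges(blocks_A)
  pe_B <- planted_edges(blocks_B)
  only_A <- setdiff(pair_keys(pe_A), pair_keys(pe_B))
  only_B <- setdiff(pair_keys(pe_B), pair_keys(pe_A))
  rewired <- sort(unique(unlist(strsplit(c(only_A, only_B), "|", fixed = TRUE))))

  # noise attenuates the latent correlation r to r / (1 + noise_sd^2)
  atten <- 1 / (1 + noise_sd^2)
  pop_sp <- lapply(list(A = blocks_A, B = blocks_B), function(bl) {
    vapply(bl, function(b) population_spearman(b$r_within * atten), numeric(1))
  })

  truth <- list(
    phenotype_labels = c(res$a$phen, res$b$phen),
    condition_labels = stats::setNames(rep(c("A", "B"), each = n), colnames(expr)),
    planted_edges_A = pe_A,
    planted_edges_B = pe_B,
    rewired_genes = rewired,
    population_spearman_within = pop_sp)
  list(expr = expr, annotations = annotations, truth = truth)
}
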