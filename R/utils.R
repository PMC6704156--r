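#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dist hclust median rnorm sd var cor.test as.dist
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom grDevices hcl.colors
#' @importFrom graphics legend par
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical form used for case-insensitive symbol matching. Firehose-style
# "SYMBOL|entrez" identifiers are reduced to the symbol part.
canon_symbol <- function(x) {
  x <- trimws(x)
  x <- sub("\\|.*$", "", x)
  toupper(x)
}

# Match requested symbols against available ones, case-insensitively, keeping
# the request order. Returns integer indices (NA for absent).
match_symbols <- function(request, available) {
  match(canon_symbol(request), canon_symbol(available))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_dcornet <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

# Competition ranking: rank 1 = largest value, ties share the minimum rank.
rank_desc_min <- function(x) rank(-x, ties.method = "min")
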