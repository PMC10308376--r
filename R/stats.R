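#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values, returned in input order. NAs propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhFdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sample location tests
#'
#' Shared test kernel for the differential stages: `rank_sum` is the two-sided
#' Wilcoxon rank-sum test (exact null distribution for small samples without
#' ties, normal approximation with tie correction otherwise), `signed_rank`
#' the paired Wilcoxon test (requires equal lengths; samples are paired by
#' position), and `t` the pooled-variance two-sample Student t-test.
#'
#' @param a,b numeric sample vectors, each of length >= 2.
#' @param kind one of `"rank_sum"`, `"signed_rank"`, `"t"`.
#' @param exact_max use the exact rank-sum distribution when
#'   `length(a) + length(b)` is at most this (default 25).
#' @return two-sided p-value. Degenerate inputs (all values tied across both
#'   samples) return 1.
#' @examples
#' rankTest(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
rankTest <- function(a, b, kind = c("rank_sum", "signed_rank", "t"),
                     exact_max = 25L) {
  kind <- match.arg(kind)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 non-missing values")
  vals <- c(a, b)
  if (max(vals) == min(vals)) return(1)
  p <- switch(kind,
    rank_sum = suppressWarnings(stats::wilcox.test(
      a, b, exact = (length(a) + length(b)) <= exact_max,
      correct = TRUE)$p.value),
    signed_rank = {
      if (length(a) != length(b))
        stop("signed_rank requires equal group sizes (paired by position)")
      d <- a - b
      if (all(d == 0)) return(1)
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                          exact = length(a) <= exact_max)$p.value)
    },
    t = {
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      stats::t.test(a, b, var.equal = TRUE)$p.value
    })
  min(1, p)
}

#' Hypergeometric over-representation analysis
#'
#' Exact upper-tail hypergeometric test of a query gene set against each set
#' of a collection, within a stated gene universe; BH FDR across sets. For a
#' set with `K` members in the universe of size `N`, a query of size `n` and
#' an overlap of `k`, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param query character vector of gene ids (must be a subset of `universe`).
#' @param sets named list of character vectors (e.g. from [readGMT()]); each
#'   set is intersected with the universe before testing.
#' @param universe character vector of all eligible gene ids.
#' @return data.frame with columns `set_name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `fdr`, sorted by p-value.
#' @export
oraTest <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(unique(as.character(sets[[nm]])), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (n == 0L || K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- do.call(rbind, res)
  out$fdr <- bhFdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member genes. Reading is
#' delegated to [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
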