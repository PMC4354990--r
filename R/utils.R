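#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm pt pf pchisq quantile rnorm runif rgamma
#'   var sd median cor dist hclust cutree as.dist cmdscale p.adjust
#'   chisq.test complete.cases setNames model.matrix ecdf
#' @importFrom utils read.delim write.table head tail
NULL

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

clamp01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

## Row-wise variance without a matrixStats dependency; x a numeric matrix.
row_vars <- function(x, means = rowMeans(x)) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - means)^2) / (n - 1)
}

row_iqr <- function(x) {
  apply(x, 1L, function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
    q[2] - q[1]
  })
}

## Dirichlet draws: n rows, one concentration vector alpha.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1), nrow = n)
  g / rowSums(g)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert and Arabie's chance-corrected agreement between two clusterings of
#' the same items; 1 for identical partitions (up to label permutation), about
#' 0 for independent ones.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## Stouffer combination of one-sided p-values (equal weights).
stouffer_p <- function(p_one_sided) {
  p <- pmin(pmax(p_one_sided, 1e-300), 1 - 1e-16)
  z <- qnorm(p, lower.tail = FALSE)
  pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
}

## Seed helper: every stochastic operation takes an explicit seed and
## restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
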