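#' Two-sided p-value for a Pearson correlation
#'
#' Student t test of `r` against zero with `n - 2` degrees of freedom,
#' the classical test behind [stats::cor.test()] for Pearson correlations.
#' Vectorised over `r`.
#'
#' @param r Pearson correlation coefficient(s), in `[-1, 1]`.
#' @param n Number of paired observations (must be >= 3).
#' @return Two-sided p-value(s) in `(0, 1]`; `|r| = 1` maps to the
#'   smallest representable positive double rather than exactly zero.
#' @export
cor_pvalue <- function(r, n) {
  if (n < 3L) stop("correlation p-value undefined for n < 3")
  r <- pmin(1, pmax(-1, r))
  df <- n - 2L
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(tstat, df = df, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same items, corrected for
#' chance; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# min-max scale a numeric vector to [0, 1]; constant input -> all 0.5
minmax_scale <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# standardize matrix rows to mean 0, sd 1; errors on zero-variance rows
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance feature(s): ",
         paste(utils::head(rownames(x)[sdv == 0], 5), collapse = ", "))
  }
  (x - mu) / sdv
}

# short content hash for manifests (md5 of a canonical JSON rendering)
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
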