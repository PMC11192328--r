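#' Two-sided Mann-Whitney U test against a control sample
#'
#' The gene-scoring primitive of the screen: each gene's sgRNA phenotypes
#' are compared to the non-targeting-control phenotypes with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. Ties are handled with midranks,
#' so \eqn{U = \#\{x_i > y_j\} + \tfrac12\#\{x_i = y_j\}}.
#'
#' In \code{"exact"} mode the p-value is computed from the full permutation
#' distribution of U over all relabelings of the pooled sample, by dynamic
#' programming over the (doubled, hence integer) midranks; because the
#' permutation distribution of U is symmetric about \eqn{n_x n_y / 2} even
#' under ties, the two-sided p-value is
#' \eqn{P(|U - n_x n_y/2| \ge |u_{obs} - n_x n_y/2|)}.
#' \code{"approx"} uses the normal approximation with the standard tie
#' correction of the variance and a 0.5 continuity correction.
#' \code{"auto"} (the default for gene scoring) selects exact when
#' \code{min(nx, ny) <= 8} and \code{nx * ny <= 10000}, else approx.
#'
#' @param x,y non-empty numeric vectors (e.g. a gene's sgRNA phenotypes
#'   and the NTC phenotypes).
#' @param mode \code{"auto"}, \code{"exact"} or \code{"approx"}.
#' @return A list with \code{U} (for \code{x} versus \code{y}),
#'   \code{p_two_sided} and the \code{mode} actually used.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")  # U = 0, p = 0.1
#' @export
mannWhitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (mode == "auto")
    mode <- if (min(nx, ny) <= 8L && nx * ny <= 10000L) "exact" else "approx"
  p <- if (mode == "exact") .mwExactP(r, nx, ny) else .mwApproxP(r, nx, ny, U)
  list(U = U, p_two_sided = p, mode = mode)
}

# Exact two-sided p from the permutation distribution of the rank sum.
# Works in doubled midranks (integers); DP over the smaller group.
.mwExactP <- function(r, nx, ny) {
  N <- nx + ny
  m <- min(nx, ny)
  r2 <- sort(as.integer(round(2 * r)))
  # doubled U deviation is the same for either group by symmetry
  Wx2 <- as.integer(round(2 * sum(r[seq_len(nx)])))
  dev <- abs((Wx2 - nx * (nx + 1)) - nx * ny)   # |2U - 2*mu|
  # dp[[k]][s+1] = number of size-k subsets of doubled ranks with sum s
  smax <- sum(r2[(N - m + 1L):N])
  dp <- vector("list", m)
  for (k in seq_len(m)) dp[[k]] <- numeric(smax + 1L)
  empty <- 1  # one subset of size 0 with sum 0
  for (i in seq_len(N)) {
    v <- r2[i]
    for (k in rev(seq_len(min(m, i)))) {
      len <- smax + 1L - v
      if (k == 1L) {
        dp[[1L]][v + 1L] <- dp[[1L]][v + 1L] + empty
      } else {
        dp[[k]][(v + 1L):(v + len)] <-
          dp[[k]][(v + 1L):(v + len)] + dp[[k - 1L]][seq_len(len)]
      }
    }
  }
  counts <- dp[[m]]
  sums <- seq_along(counts) - 1L
  devs <- abs((sums - m * (m + 1L)) - m * (N - m))
  sum(counts[devs >= dev - 1e-9]) / choose(N, m)
}

# Normal approximation with tie-corrected variance + continuity correction.
.mwApproxP <- function(r, nx, ny, U) {
  N <- nx + ny
  mu <- nx * ny / 2
  tie <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}
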