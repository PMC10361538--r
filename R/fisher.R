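#' Two-sided Fisher exact test for 2x2 tables, vectorised
#'
#' Exact conditional test on the table `[a, b; c, d]`. The two-sided p-value
#' is defined by summing hypergeometric point probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of the
#' observed table — the conventional definition, stated here because
#' implementations differ. A relative tolerance of 1e-7 guards the
#' probability comparison against floating-point ties, matching common
#' practice.
#'
#' @param a,b,c,d Integer vectors (recycled) of cell counts: `a` and `b` form
#'   row one, `c` and `d` row two.
#' @param alternative `"two.sided"` (default) or `"greater"` (upper tail of
#'   `a`).
#' @return Numeric vector of p-values.
#' @examples
#' fisher_exact(5, 5, 0, 10)  # 0.03250…
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    abort("cell counts must be non-negative", class = "tilmotif_stat_error")
  }
  m <- a + b          # row-1 total (white balls)
  nn <- c + d         # row-2 total (black balls)
  k <- a + c          # column-1 total (balls drawn)
  if (alternative == "greater") {
    return(phyper(a - 1, m, nn, k, lower.tail = FALSE))
  }
  vapply(seq_len(n), function(i) {
    lo <- max(0, k[i] - nn[i])
    hi <- min(k[i], m[i])
    support <- lo:hi
    pmf <- dhyper(support, m[i], nn[i], k[i])
    d_obs <- pmf[support == a[i]]
    min(1, sum(pmf[pmf <= d_obs * (1 + 1e-7)]))
  }, numeric(1))
}
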