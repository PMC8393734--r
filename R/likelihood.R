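# Multinomial read-group likelihood and effective lengths for
# skipped-exon (SE) events.
#
# For one event in one cell the three group counts s = (s1, s2, s3) are
# multinomial with proportions rho(psi, L), where psi is the inclusion
# ratio and L the 2 x 3 effective-length matrix: row h, column k counts
# the read start positions on isoform h that yield a read of group k.
# The multinomial coefficient is omitted throughout: it does not depend
# on psi, so it cancels in gradients and in ELBO differences between
# models fitted to the same data. Reported (log-)likelihoods and ELBOs
# are therefore comparable only within a dataset.

#' Effective lengths of a skipped-exon event
#'
#' Counts, by explicit enumeration of every read start position, how many
#' positions on the inclusion isoform (exons 1-2-3) and the exclusion
#' isoform (exons 1-3) produce a read of each identity group, for
#' single-end reads of length `read_len`. A read is isoform-1-unique when
#' it overlaps exon 2 by at least `overhang` nucleotides, isoform-2-unique
#' when it spans the exon1-exon3 junction with at least `overhang`
#' nucleotides on each side. Reads producible by both isoforms (entirely
#' within exon 1 or exon 3) are ambiguous, as are low-confidence reads
#' (exon-2 overlap or junction overhang below `overhang`), which are
#' counted into the ambiguous column of both isoforms symmetrically so
#' that `l13 = l23` holds in every geometry.
#'
#' With `overhang = 1` (the default) no low-confidence class exists and
#' the closed forms `l11 = e2 + r - 1`, `l22 = r - 1`,
#' `l13 = l23 = e1 + e3 - 2 r + 2` are exact whenever `min(e1, e3) >= r`;
#' see `method = "closed"`.
#'
#' @param e1,e2,e3 Positive integer exon lengths (nt).
#' @param read_len Positive integer read length `r` (nt).
#' @param overhang Minimum junction/overlap support `h` in nt (default 1).
#' @param method `"enumerate"` (authoritative; default) or `"closed"` (fast
#'   closed forms, valid when `min(e1, e3) >= r`, `e2 >= overhang` and
#'   `read_len >= 2 * overhang`).
#' @return A 2 x 3 numeric matrix `L` with rows = isoforms (inclusion,
#'   exclusion) and columns = read groups (isoform-1-unique,
#'   isoform-2-unique, ambiguous); `L[1,2] = L[2,1] = 0` and
#'   `L[1,3] = L[2,3]` always.
#' @export
#' @examples
#' effective_lengths_se(100, 50, 100, read_len = 10)
effective_lengths_se <- function(e1, e2, e3, read_len, overhang = 1L,
                                 method = c("enumerate", "closed")) {
  method <- match.arg(method)
  stopifnot(e1 >= 1, e2 >= 1, e3 >= 1, read_len >= 1, overhang >= 1)
  r <- as.integer(read_len); h <- as.integer(overhang)
  if (r < 2L * h)
    warning("read_len < 2 * overhang: no junction read can be isoform-2-unique (l22 = 0)")
  if (method == "closed") {
    if (min(e1, e3) < r || e2 < h || r < 2L * h - 1L)
      stop("closed forms require min(e1, e3) >= read_len, e2 >= overhang and read_len >= 2 * overhang - 1; use method = \"enumerate\"")
    l11 <- e2 + r - 2L * h + 1L
    l22 <- r - 2L * h + 1L
    l13 <- (e1 - r + 1L) + (e3 - r + 1L) + 4L * (h - 1L)
    return(matrix(c(l11, 0, l13, 0, l22, l13), 2, 3, byrow = TRUE))
  }
  # inclusion isoform: e1 + e2 + e3
  n1 <- e1 + e2 + e3 - r + 1L
  l11 <- 0L; low1 <- 0L; shared1 <- 0L
  if (n1 >= 1L) {
    p <- seq_len(n1)
    ov <- pmin(p + r - 1L, e1 + e2) - pmax(p, e1 + 1L) + 1L
    ov[ov < 0L] <- 0L
    l11 <- sum(ov >= h)
    low1 <- sum(ov >= 1L & ov < h)
    shared1 <- sum(ov == 0L)
  }
  # exclusion isoform: e1 + e3
  n2 <- e1 + e3 - r + 1L
  l22 <- 0L; low2 <- 0L; shared2 <- 0L
  if (n2 >= 1L) {
    p <- seq_len(n2)
    spans <- p <= e1 & (p + r - 1L) >= e1 + 1L
    a <- e1 - p + 1L   # junction overhang in exon 1
    b <- r - a         # junction overhang in exon 3
    l22 <- sum(spans & a >= h & b >= h)
    low2 <- sum(spans & (a < h | b < h))
    shared2 <- sum(!spans)
  }
  # shared1 == shared2 by construction (reads entirely within exon 1 or 3)
  l13 <- shared1 + low1 + low2
  matrix(as.numeric(c(l11, 0, l13, 0, l22, l13)), 2, 3, byrow = TRUE)
}

#' Effective-length matrix used in velocity mode
#'
#' Spliced and unspliced counts arrive pre-assigned by the upstream
#' counter, so there is no ambiguous group and unit lengths are used:
#' `rho = (psi, 1 - psi, 0)`.
#'
#' @return The 2 x 3 matrix `[[1,0,0],[0,1,0]]`.
#' @export
velocity_lengths <- function() {
  matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
}

#' Read-group proportions for one event
#'
#' The multinomial proportion of group `k` is proportional to
#' `psi * L[1, k] + (1 - psi) * L[2, k]`, normalised over the three groups.
#'
#' @param psi Inclusion ratio in `[0, 1]`.
#' @param L 2 x 3 non-negative effective-length matrix.
#' @return Numeric 3-vector summing to 1.
#' @export
#' @examples
#' compute_rho(0.5, matrix(c(2, 0, 1, 0, 2, 1), 2, 3, byrow = TRUE))
compute_rho <- function(psi, L) {
  stopifnot(length(psi) == 1L, psi >= 0, psi <= 1,
            is.matrix(L), all(dim(L) == c(2L, 3L)), all(L >= 0))
  num <- psi * L[1, ] + (1 - psi) * L[2, ]
  tot <- sum(num)
  if (tot <= 0)
    stop("degenerate mixture: psi-weighted effective lengths are all zero")
  num / tot
}

#' Multinomial log-likelihood of grouped counts (constant omitted)
#'
#' Returns `sum_k s_k * log(rho_k)` with `rho = compute_rho(psi, L)`.
#' Terms with `s_k = 0` contribute 0 even when `rho_k = 0`; the result is
#' `-Inf` exactly when some `s_k > 0` has `rho_k = 0`. The multinomial
#' coefficient `log(n! / (s1! s2! s3!))` is omitted (constant in `psi`).
#'
#' @param s Non-negative integer count 3-vector.
#' @param psi Inclusion ratio in `[0, 1]`.
#' @param L 2 x 3 effective-length matrix.
#' @return Scalar log-likelihood.
#' @export
splice_loglik <- function(s, psi, L) {
  stopifnot(length(s) == 3L, all(s >= 0), all(s == round(s)))
  if (all(s == 0)) return(0)
  rho <- compute_rho(psi, L)
  pos <- s > 0
  if (any(rho[pos] == 0)) return(-Inf)
  sum(s[pos] * log(rho[pos]))
}
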