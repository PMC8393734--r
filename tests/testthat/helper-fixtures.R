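# Fixture builders: all test data is generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# SplicingCountData from dense group matrices and one shared 2 x 3
# effective-length matrix.
make_scd <- function(s1, s2, s3, L, cell_ids = NULL, event_ids = NULL) {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2); s3 <- as.matrix(s3)
  N <- ncol(s1)
  lengths <- matrix(rep(c(L[1, ], L[2, ]), each = N), N, 6)
  splicing_count_data(s1, s2, s3, lengths,
                      cell_ids = cell_ids %||% paste0("c", seq_len(nrow(s1))),
                      event_ids = event_ids %||% paste0("e", seq_len(N)))
}

# Multinomial group counts for given per-cell totals and a single psi/L;
# returns a cells x 3 matrix. Plain rmultinom, independent of the
# package's sequential-binomial sampler.
rmultinom_groups <- function(n, psi, L) {
  rho <- compute_rho(psi, L)
  t(vapply(n, function(ni) as.numeric(stats::rmultinom(1, ni, rho)),
           numeric(3)))
}

# One-event dataset with counts drawn at the given psi values (one per
# cell), unit-free of the simulate module.
make_one_event <- function(psi, n, L, seed = 1L) {
  set.seed(seed)
  M <- length(psi)
  s <- matrix(0, M, 3)
  for (c in seq_len(M)) s[c, ] <- rmultinom_groups(n[c], psi[c], L)
  make_scd(s[, 1, drop = FALSE], s[, 2, drop = FALSE], s[, 3, drop = FALSE], L)
}

# Default skipped-exon geometry shared by several tests.
default_L <- function() effective_lengths_se(500, 100, 500, read_len = 100)
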