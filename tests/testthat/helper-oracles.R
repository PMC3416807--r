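# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive computation (inclusion-exclusion, step-up rule spelled
# out, exhaustive counting) kept separate from the package's own code paths.

# ALE by inclusion-exclusion. coord_sets: list of per-experiment n x 3 mm
# matrices. Per experiment, P(union of focus kernels) is expanded over all
# non-empty focus subsets; experiments are then combined the same way over
# modeled-activation values. Only evaluated at `voxels` (matrix of 1-based
# voxel indices) to keep the 2^n expansion small.
ale_oracle <- function(coord_sets, grid, fwhm, voxels) {
  kern_at <- function(focus) {
    k <- gaussian_kernel_map(grid, focus, fwhm)
    k$values[voxels]
  }
  union_ie <- function(vals) {
    # vals: list of numeric vectors (one per event)
    n <- length(vals)
    total <- 0
    for (sz in seq_len(n)) {
      for (sel in utils::combn(n, sz, simplify = FALSE)) {
        total <- total + (-1)^(sz + 1) * Reduce(`*`, vals[sel])
      }
    }
    total
  }
  ma <- lapply(coord_sets, function(xyz) {
    union_ie(lapply(seq_len(nrow(xyz)), function(r) kern_at(xyz[r, ])))
  })
  union_ie(ma)
}

# Benjamini-Hochberg step-up spelled out: largest k with p_(k) <= q k / m;
# reject all hypotheses with p <= p_(k).
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= q * seq_len(m) / m)
  rejected <- logical(m)
  if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

# Dense random symmetric 2-block similarity matrix for reordering checks.
block_similarity <- function(sizes, within = 0.9, between = 0.1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- matrix(between, n, n)
  for (g in seq_along(sizes)) S[lab == g, lab == g] <- within
  diag(S) <- 1
  rownames(S) <- colnames(S) <- sprintf("n%02d", seq_len(n))
  list(S = S, labels = lab)
}

# Exhaustive counting versions of the corpus statistics.
forward_oracle <- function(corpus, term, region) {
  t_set <- which(corpus[[term]] == 1)
  sum(corpus[[region]][t_set] == 1) / length(t_set)
}
reverse_oracle_empirical <- function(corpus, term, region) {
  act <- which(corpus[[region]] == 1)
  sum(corpus[[term]][act] == 1) / length(act)
}
jaccard_oracle <- function(corpus, a, b) {
  sa <- which(corpus[[a]] == 1); sb <- which(corpus[[b]] == 1)
  u <- length(union(sa, sb))
  if (u == 0) 0 else length(intersect(sa, sb)) / u
}
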