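# Independent brute-force oracles, written deliberately apart from the
# package implementations they check.

# TMM by explicit loops and sort-based trimming
brute_tmm <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  counts <- counts[apply(counts, 1, function(r) any(r > 0)), , drop = FALSE]
  N <- apply(counts, 2, sum)
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    uq[j] <- stats::quantile(counts[, j], 0.75) / N[j]
  }
  r <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- A <- w <- c()
    for (g in seq_len(nrow(counts))) {
      yj <- counts[g, j]; yr <- counts[g, r]
      if (yj > 0 && yr > 0) {
        M <- c(M, log2((yj / N[j]) / (yr / N[r])))
        A <- c(A, 0.5 * log2((yj / N[j]) * (yr / N[r])))
        w <- c(w, 1 / ((N[j] - yj) / (N[j] * yj) + (N[r] - yr) / (N[r] * yr)))
      }
    }
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    # midrank by explicit counting (ties share one rank, kept or cut together)
    midrank <- function(x, i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    keep <- c()
    for (g in seq_len(n)) {
      rM <- midrank(M, g); rA <- midrank(A, g)
      if (rM >= floor(n * m_trim) + 1 && rM <= n - floor(n * m_trim) &&
          rA >= floor(n * a_trim) + 1 && rA <= n - floor(n * a_trim)) {
        keep <- c(keep, g)
      }
    }
    f[j] <- 2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# O(m^2) Benjamini-Hochberg: q_i = min over all j with p_j >= p_i of m*p_j/rank_j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- c()
    for (k in seq_len(m)) {
      if (p[o[k]] >= p[o[i]] || k >= i) {
        if (k >= i) cand <- c(cand, m * p[o[k]] / k)
      }
    }
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# fabricate a contrast spec directly (internal constructor)
make_contrast <- function(grp, ref, kind = "vs_rest") {
  myoCytokines:::contrast_spec(
    name = "test", group_samples = grp, reference_samples = ref, kind = kind
  )
}

# small deterministic count matrix with distinct entries
toy_counts <- function(n_genes = 6, n_samples = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(
    stats::rpois(n_genes * n_samples, lambda = stats::runif(n_genes, 5, 200)),
    nrow = n_genes,
    dimnames = list(paste0("g", seq_len(n_genes)), paste0("s", seq_len(n_samples)))
  )
  storage.mode(m) <- "integer"
  m
}

# annotation table matching the full study design sizes
table1_annotations <- function() {
  sizes <- table1_group_sizes()
  memb <- myoCytokines:::leaf_membership()
  leaves <- rep(names(sizes), sizes)
  idx <- match(leaves, memb$leaf)
  data.frame(
    sample_id = sprintf("P%04d", seq_along(leaves)),
    clinical_group = memb$clinical_group[idx],
    autoantibody_subgroup = memb$autoantibody_subgroup[idx],
    stringsAsFactors = FALSE
  )
}
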