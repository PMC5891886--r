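# Independent oracles, kept separate from the package's own implementations.

# All permutations of 1..n, built by iterative insertion (distinct from the
# package's recursive prefix enumerator).
oracle_permutations <- function(n) {
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(perms) * k, k)
    row <- 1L
    for (i in seq_len(nrow(perms))) {
      for (pos in seq_len(k)) {
        out[row, ] <- append(perms[i, ], k, after = pos - 1L)
        row <- row + 1L
      }
    }
    perms <- out
  }
  perms
}

# Spearman rho for untied data from the classical sum-of-squared-rank-
# differences formula (no call to cor()).
oracle_spearman_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exact two-sided permutation p-value: share of all n! rank assignments with
# |rho| at least the observed |rho|.
oracle_perm_p <- function(x, y) {
  n <- length(x)
  perms <- oracle_permutations(n)
  obs <- abs(oracle_spearman_rho(x, y))
  ry <- rank(y)
  rhos <- apply(perms, 1L, function(p) oracle_spearman_rho(seq_len(n), ry[p]))
  mean(abs(rhos) >= obs - 1e-12)
}

# Quartile by direct sorted linear interpolation at h = (n - 1) p + 1.
oracle_quartile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Small well-formed spot table: one case/compartment, a panel of endpoints
# on ideal 2-fold curves, plus ssDNA and negative-control rows. The panel is
# large enough for the negative-control QC screen to have power.
tiny_spot_table <- function(case = "c1", comp = "epithelium",
                            tops = c(AKT = 8, ERK = 4, P38 = 6, JNK = 2,
                                     STAT3 = 10, SRC = 5),
                            ssdna = 2, nc = 0.05) {
  steps <- 0:3
  ep_rows <- do.call(rbind, lapply(names(tops), function(ep) {
    data.frame(case_id = case, compartment = comp, stain = ep,
               dilution_step = steps, replicate = 1L,
               raw_intensity = tops[[ep]] / 2^steps)
  }))
  rbind(
    ep_rows,
    data.frame(case_id = case, compartment = comp, stain = "ssDNA",
               dilution_step = steps, replicate = 1L, raw_intensity = ssdna),
    data.frame(case_id = case, compartment = comp,
               stain = "negative_control", dilution_step = steps,
               replicate = 1L, raw_intensity = nc)
  )
}
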