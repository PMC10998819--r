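# Independent brute-force oracles and small fixtures used across tests.
# The oracles deliberately share no code with the package implementations.

# One-way PERMANOVA pseudo-F by the naive double-loop sum-of-squares
# decomposition of the distance matrix.
naive_permanova_F <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  g <- as.character(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ss_total <- ss_total + dmat[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) >= 2) {
      acc <- 0
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        acc <- acc + dmat[idx[a], idx[b]]^2
      }
      ss_within <- ss_within + acc / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(g))
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Exact one-way PERMANOVA p-value by enumerating every relabelling
# (identity included).
enumerate_permanova_p <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  f_obs <- naive_permanova_F(dmat, groups)
  perms <- gen_all_perms(n)
  f_all <- apply(perms, 1, function(p) naive_permanova_F(dmat, groups[p]))
  mean(f_all >= f_obs - 1e-12)
}

# Exact Mantel p by full enumeration: permute rows/columns of m2 jointly,
# Spearman correlation of lower triangles each time.
enumerate_mantel <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt], method = "spearman")
  perms <- gen_all_perms(n)
  r_all <- apply(perms, 1, function(p) {
    cor(m1[lt], m2[p, p][lt], method = "spearman")
  })
  list(r = r_obs, p = mean(r_all >= r_obs - 1e-12))
}

# Plain recursive permutation generator (independent of the package's).
gen_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gen_all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub)))
  }))
}

# Brute-force Kikvidze-Ohsawa deviation scan, written directly from the
# equal-share definition.
brute_ko <- function(x, ideal = "total") {
  x <- sort(x, decreasing = TRUE)
  n <- length(x)
  dev <- sapply(seq_len(n), function(k) {
    m <- if (ideal == "total") 1 / k else sum(x[1:k]) / k
    sum((x[1:k] - m)^2) + sum(x[-(1:k)]^2)
  })
  list(k = which.min(dev), dev = dev)
}

# Small count-table fixture written to a temp file.
write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Compact simulation configuration for fast tests.
tiny_config <- function(seed = 1, ...) {
  simulation_config(
    seed = seed,
    sites = "siteA",
    months = c("May", "July", "September"),
    site_months = list(siteA = c("May", "July", "September")),
    n_otus = 60,
    n_dominant = 5,
    dominant_mean_props = c(0.20, 0.15, 0.05, 0.03, 0.02),
    n_seasonal = 4,
    comp_pref_otus = c(2L, 10:20),
    ph_otus = 1:2,
    depth_range = c(2000L, 4000L),
    ...
  )
}
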