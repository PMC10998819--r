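# Distance matrices and permutation-based community statistics:
# PERMANOVA (global, pairwise), Mantel, RDA, NMDS.

#' Compute a community or environment distance matrix
#'
#' Bray-Curtis for community composition (rows should be per-sample
#' relative abundances; non-negative input required) or Euclidean on
#' z-standardised columns for environmental variables.
#'
#' @param x numeric matrix, samples in rows.
#' @param metric "bray" or "euclidean".
#' @param standardize z-score columns before Euclidean distance (default
#'   `TRUE` for Euclidean, ignored for Bray-Curtis).
#' @return a `dist` object with a `metric` attribute.
#' @export
distance_matrix <- function(x, metric = c("bray", "euclidean"), standardize = NULL) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two samples")
  if (metric == "bray") {
    if (any(x < 0)) stop("Bray-Curtis requires non-negative input")
    d <- vegan::vegdist(x, method = "bray")
  } else {
    standardize <- standardize %||% TRUE
    if (standardize) {
      sds <- apply(x, 2L, stats::sd)
      if (any(sds == 0)) {
        stop("zero-variance column(s): ",
             paste(colnames(x)[sds == 0], collapse = ", "))
      }
      x <- scale(x)
    }
    d <- stats::dist(x)
  }
  attr(d, "metric") <- metric
  d
}

# Gower-centred inner-product matrix of squared distances; its trace is the
# total sum of squares partitioned by PERMANOVA.
gower_center <- function(m) {
  a <- -0.5 * m^2
  n <- nrow(a)
  rm_ <- rowMeans(a); gm <- mean(a)
  a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
}

# Hat matrix of a design matrix via QR (rank-revealing).
hat_matrix <- function(X) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = qrX$rank)
}

permutation_set <- function(n, n_perm, seed, exhaustive, strata = NULL) {
  if (exhaustive) {
    if (!is.null(strata)) stop("strata not supported in exhaustive mode")
    return(all_permutations(n))
  }
  with_rng_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      if (is.null(strata)) {
        sample.int(n)
      } else {
        p <- seq_len(n)
        for (lev in unique(strata)) {
          idx <- which(strata == lev)
          p[idx] <- idx[sample.int(length(idx))]
        }
        p
      }
    }, integer(n)))
  })
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squares of a distance matrix among model
#' terms sequentially (Type I, in the order given), computing a pseudo-F
#' per term from the Gower-centred matrix and testing it by whole-row
#' label permutation. The p-value includes the observed ordering:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). With
#' `exhaustive = TRUE` all n! permutations are enumerated (n <= 8) and p
#' is the exact proportion, identity included.
#'
#' @param d distance matrix (`dist` or square symmetric matrix).
#' @param factors data.frame of design factors, rows aligned with `d`
#'   (matched by row names / labels when both are present).
#' @param terms character vector of term labels evaluated sequentially
#'   (columns of `factors`, interactions as "a:b"); defaults to all
#'   columns of `factors` in order.
#' @param n_perm number of random permutations.
#' @param seed RNG seed for reproducible permutations.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @param strata optional blocking factor; permutations are restricted to
#'   within-block shuffles.
#' @return `amf_permanova`: data.frame with per-term `df`, `SS`, `R2`,
#'   `F`, `p` plus Residual and Total rows; attributes record `n_perm` and
#'   `seed`.
#' @export
permanova <- function(d, factors, terms = NULL, n_perm = 999, seed = NULL,
                      exhaustive = FALSE, strata = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  factors <- as.data.frame(factors)
  if (nrow(factors) != n) stop("factors must have one row per sample in d")
  dl <- attr(d, "Labels") %||% rownames(m)
  if (!is.null(dl) && !is.null(rownames(factors)) &&
      !all(rownames(factors) == as.character(seq_len(n)))) {
    if (!setequal(dl, rownames(factors))) {
      stop("sample ids of d and factors differ")
    }
    factors <- factors[match(dl, rownames(factors)), , drop = FALSE]
  }
  terms <- terms %||% names(factors)
  if (!length(terms)) stop("no model terms")

  G <- gower_center(m)
  ss_total <- sum(diag(G))

  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (j in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(j)]), data = factors)
    hm <- hat_matrix(X)
    hats[[j]] <- hm$H
    ranks[j] <- hm$rank
  }
  df_terms <- diff(c(1L, ranks))
  if (any(df_terms == 0L)) {
    stop("term(s) confounded with earlier terms: ",
         paste(terms[df_terms == 0L], collapse = ", "))
  }
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0L) stop("no residual degrees of freedom")

  term_stats <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    list(F = (ss / df_terms) / (ss_res / df_res), ss = ss, ss_res = ss_res)
  }
  obs <- term_stats(G)

  perms <- permutation_set(n, n_perm, seed, exhaustive, strata)
  f_perm <- matrix(NA_real_, nrow(perms), length(terms))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    f_perm[i, ] <- term_stats(G[p, p])$F
  }
  eps <- 1e-12
  p_val <- if (exhaustive) {
    colMeans(f_perm >= rep(obs$F, each = nrow(f_perm)) - eps)
  } else {
    (1 + colSums(f_perm >= rep(obs$F, each = nrow(f_perm)) - eps)) / (1 + nrow(perms))
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$F, NA, NA),
    p = c(p_val, NA, NA),
    stringsAsFactors = FALSE)
  structure(out, class = c("amf_permanova", "data.frame"),
            n_perm = if (exhaustive) nrow(perms) else n_perm,
            exhaustive = exhaustive, seed = seed)
}

#' Pairwise PERMANOVA over the levels of one factor
#'
#' Runs [permanova()] on every pair of factor levels and adjusts the
#' p-values for the number of pairs.
#'
#' @param d distance matrix.
#' @param factor_values grouping vector aligned with `d`.
#' @param n_perm permutations per pair.
#' @param seed master seed; each pair uses a derived sub-stream.
#' @param adjust p-adjustment method ("bonferroni", "BH", ..., or "none").
#' @return data.frame with one row per level pair: `F`, `R2`, `p_raw`,
#'   `p_adj`.
#' @export
pairwise_permanova <- function(d, factor_values, n_perm = 999, seed = NULL,
                               adjust = "bonferroni") {
  m <- as_dist_matrix(d)
  g <- factor(factor_values)
  if (nrow(m) != length(g)) stop("factor length must match d")
  lev <- levels(g)
  if (length(lev) < 2L) stop("need at least two levels")
  pairs <- utils::combn(lev, 2L)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    sel <- g %in% pairs[, k]
    if (min(table(droplevels(g[sel]))) < 2L) {
      stop("pair ", paste(pairs[, k], collapse = "-"),
           " has fewer than two samples in a level")
    }
    sub_seed <- if (is.null(seed)) NULL else substream_seed(seed, k, stream = 4L)
    fit <- permanova(m[sel, sel, drop = FALSE],
                     data.frame(g = droplevels(g[sel])),
                     n_perm = n_perm, seed = sub_seed)
    res[[k]] <- data.frame(level1 = pairs[1L, k], level2 = pairs[2L, k],
                           F = fit$F[1L], R2 = fit$R2[1L], p_raw = fit$p[1L],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adj <- if (identical(adjust, "none")) out$p_raw else
    stats::p.adjust(out$p_raw, method = adjust)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Mantel test between two distance matrices
#'
#' Correlates the lower triangles of two distance matrices (Spearman rank
#' correlation by default) and obtains a one-sided p-value by jointly
#' permuting the rows and columns of the second matrix. `exhaustive = TRUE`
#' enumerates all n! permutations (n <= 8) and returns the exact
#' proportion, identity included.
#'
#' @param d1,d2 distance matrices over the same samples in the same order.
#' @param method "spearman" or "pearson".
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @param exhaustive enumerate all permutations.
#' @return `amf_mantel`: list with `r`, `p`, `n_perm`, `method`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = NULL, exhaustive = FALSE) {
  method <- match.arg(method)
  m1 <- as_dist_matrix(d1, "d1")
  m2 <- as_dist_matrix(d2, "d2")
  n <- nrow(m1)
  if (nrow(m2) != n) stop("d1 and d2 differ in size")
  l1 <- attr(d1, "Labels") %||% rownames(m1)
  l2 <- attr(d2, "Labels") %||% rownames(m2)
  if (!is.null(l1) && !is.null(l2) && !all(l1 == l2)) {
    stop("d1 and d2 sample ids differ or are ordered differently")
  }
  if (n < 4L) stop("Mantel test needs at least 4 samples")
  ltri <- lower.tri(m1)
  if (method == "spearman") {
    M1 <- matrix(0, n, n); M1[ltri] <- rank(m1[ltri]); M1 <- M1 + t(M1)
    M2 <- matrix(0, n, n); M2[ltri] <- rank(m2[ltri]); M2 <- M2 + t(M2)
  } else {
    M1 <- m1; M2 <- m2
  }
  x <- M1[ltri]
  y0 <- M2[ltri]
  if (stats::sd(x) == 0 || stats::sd(y0) == 0) {
    stop("constant lower triangle: correlation undefined")
  }
  r_obs <- stats::cor(x, y0)
  perms <- permutation_set(n, n_perm, seed, exhaustive)
  r_perm <- vapply(seq_len(nrow(perms)), function(i) {
    p <- perms[i, ]
    stats::cor(x, M2[p, p][ltri])
  }, numeric(1))
  eps <- 1e-12
  p_val <- if (exhaustive) mean(r_perm >= r_obs - eps) else
    (1 + sum(r_perm >= r_obs - eps)) / (1 + length(r_perm))
  structure(list(r = r_obs, p = p_val,
                 n_perm = if (exhaustive) nrow(perms) else n_perm,
                 method = method, exhaustive = exhaustive, seed = seed),
            class = "amf_mantel")
}

#' @export
print.amf_mantel <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%s%d permutations)\n",
              x$method, x$r, x$p, if (x$exhaustive) "exhaustive " else "", x$n_perm))
  invisible(x)
}

#' Redundancy analysis with permutation test and per-OTU correlations
#'
#' Column-centres the community matrix (per-sample relative abundances),
#' z-standardises the environment matrix, and eigen-decomposes the fitted
#' values of the multivariate regression of community on environment.
#' Axis variances are reported as proportions of the total community
#' variance; constrained plus unconstrained proportions sum to one. The
#' overall model pseudo-F is tested by permuting sample rows of the
#' (centred) community matrix. A per-OTU table reports the rank
#' correlation of each OTU's relative abundance with each environment
#' variable with a two-sided permutation p-value, flagging coefficients of
#' magnitude at least `cor_threshold`.
#'
#' @param community samples x OTUs relative-abundance matrix.
#' @param environment samples x variables numeric matrix or data.frame.
#' @param n_perm permutations for the model test and per-OTU p-values.
#' @param seed RNG seed.
#' @param cor_threshold flag per-OTU correlations at or above this
#'   magnitude.
#' @param adjust p-adjustment for the per-OTU table ("none" keeps raw
#'   permutation p-values; "BH" etc. as in [stats::p.adjust()]).
#' @return `amf_rda`: list with constrained/unconstrained eigenvalues and
#'   axis proportions, `constrained_prop` (model R2), `F`, `p`, score
#'   matrices, and `otu_env` correlation table.
#' @export
rda_analysis <- function(community, environment, n_perm = 999, seed = NULL,
                         cor_threshold = 0.5, adjust = "none") {
  Y <- as.matrix(community)
  X <- as.matrix(as.data.frame(environment))
  n <- nrow(Y)
  if (nrow(X) != n) stop("community and environment row counts differ")
  if (n <= ncol(X) + 1L) stop("need more samples than environment variables + 1")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance environment column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Xs <- scale(X)
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1L) {
    stop("collinear environment columns (design rank ", qrX$rank - 1L,
         " < ", ncol(Xs), ")")
  }
  q <- ncol(Xs)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  fitted <- qr.fitted(qrX, Yc)
  resid <- Yc - fitted
  ss_total <- sum(Yc^2)
  if (ss_total == 0) stop("community matrix has zero variance")
  sv <- svd(fitted)
  # fitted values have rank at most q (Yc is centred, so the intercept
  # contributes nothing); later singular values are numerical zeros
  eig_c <- sv$d[seq_len(q)]^2
  eig_u <- svd(resid, nu = 0, nv = 0)$d^2
  eig_u <- eig_u[eig_u > 1e-14 * ss_total]

  ss_fit <- sum(fitted^2)
  ss_res <- ss_total - ss_fit
  df_res <- n - 1L - q
  f_obs <- (ss_fit / q) / (ss_res / df_res)
  perms <- permutation_set(n, n_perm, seed, exhaustive = FALSE)
  f_perm <- vapply(seq_len(nrow(perms)), function(i) {
    Yp <- Yc[perms[i, ], , drop = FALSE]
    ssf <- sum(qr.fitted(qrX, Yp)^2)
    (ssf / q) / ((ss_total - ssf) / df_res)
  }, numeric(1))
  p_model <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)

  axes <- seq_len(q)
  sample_scores <- sv$u[, axes, drop = FALSE] %*% diag(sv$d[axes], nrow = length(axes))
  rownames(sample_scores) <- rownames(Y)
  colnames(sample_scores) <- paste0("RDA", axes)
  otu_scores <- sv$v[, axes, drop = FALSE]
  rownames(otu_scores) <- colnames(Y)
  colnames(otu_scores) <- paste0("RDA", axes)
  env_scores <- stats::cor(Xs, sample_scores)

  otu_env <- otu_env_correlations(Y, X, n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL else substream_seed(seed, 1L, 5L),
                                  cor_threshold = cor_threshold, adjust = adjust)

  structure(list(
    eig_constrained = eig_c,
    eig_unconstrained = eig_u,
    axis_props = eig_c / ss_total,
    unconstrained_props = eig_u / ss_total,
    constrained_prop = ss_fit / ss_total,
    first_two_axes_prop = sum((eig_c / ss_total)[seq_len(min(2L, length(eig_c)))]),
    F = f_obs, p = p_model, n_perm = n_perm, seed = seed,
    scores = list(samples = sample_scores, otus = otu_scores, environment = env_scores),
    otu_env = otu_env),
    class = "amf_rda")
}

# Rank correlations of each OTU with each environment variable, permutation
# p-values (two-sided) sharing one permutation set per variable.
otu_env_correlations <- function(Y, X, n_perm = 999, seed = NULL,
                                 cor_threshold = 0.5, adjust = "none",
                                 method = "spearman") {
  n <- nrow(Y)
  rank_std <- function(v) {
    r <- rank(v)
    r <- r - mean(r)
    s <- sqrt(sum(r^2))
    if (s == 0) rep(0, length(r)) else r / s
  }
  otu_ids <- colnames(Y) %||% sprintf("OTU%04d", seq_len(ncol(Y)))
  RY <- apply(Y, 2L, rank_std)
  perms <- permutation_set(n, n_perm, seed, exhaustive = FALSE)
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    rx <- rank_std(X[, j])
    r_obs <- as.vector(crossprod(RY, rx))
    exceed <- integer(length(r_obs))
    for (i in seq_len(nrow(perms))) {
      r_p <- as.vector(crossprod(RY, rx[perms[i, ]]))
      exceed <- exceed + (abs(r_p) >= abs(r_obs) - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
    out[[j]] <- data.frame(otu_id = otu_ids,
                           variable = colnames(X)[j] %||% paste0("V", j),
                           r = r_obs, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$p_adj <- if (identical(adjust, "none")) out$p else
    stats::p.adjust(out$p, method = adjust)
  out$flagged <- abs(out$r) >= cor_threshold
  rownames(out) <- NULL
  out
}

#' @export
print.amf_rda <- function(x, ...) {
  cat(sprintf("RDA: constrained %.1f%% of total variance (first two axes %.1f%%)\n",
              100 * x$constrained_prop, 100 * x$first_two_axes_prop))
  cat(sprintf("model pseudo-F = %.3f, permutation p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_perm))
  cat(sum(x$otu_env$flagged), "OTU-environment correlations with |r| >=",
      attr(x$otu_env, "threshold") %||% 0.5, "\n")
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Global NMDS minimising Kruskal stress-1 by iterative majorisation with
#' monotone regression, run from a metric-scaling start plus
#' `restarts - 1` seeded random starts; the lowest-stress solution is
#' returned, so stress is non-increasing in the number of restarts.
#'
#' @param d distance matrix (`dist` or square symmetric matrix).
#' @param k embedding dimension (default 2).
#' @param restarts total number of starts (>= 1).
#' @param maxit maximum iterations per start.
#' @param seed RNG seed for the random starts.
#' @return `amf_nmds`: list with `points` (n x k coordinates), `stress`
#'   (Kruskal stress-1), `n_restarts`, `converged`.
#' @export
nmds_ordination <- function(d, k = 2L, restarts = 20L, maxit = 500L, seed = NULL) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as_dist_matrix(d))
  n <- attr(d, "Size")
  if (n < k + 2L) stop("need at least k + 2 samples")
  # explicit metric-scaling start, rounded so the descent is bit-stable
  # irrespective of the linear-algebra backend's reduction order
  y_start <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(y_start) < k) {
    y_start <- cbind(y_start, matrix(0, n, k - ncol(y_start)))
  }
  y_start <- round(y_start, 9)
  best <- vegan::monoMDS(d, y = y_start, k = k, model = "global", maxit = maxit)
  if (restarts > 1L) {
    with_rng_seed(seed, {
      for (j in seq_len(restarts - 1L)) {
        y0 <- matrix(stats::rnorm(n * k), n, k)
        fit <- try(vegan::monoMDS(d, y = y0, k = k, model = "global", maxit = maxit),
                   silent = TRUE)
        if (!inherits(fit, "try-error") && fit$stress < best$stress) best <- fit
      }
    })
  }
  structure(list(points = best$points, stress = best$stress,
                 n_restarts = restarts,
                 converged = best$iters < maxit, seed = seed),
            class = "amf_nmds")
}

#' @export
print.amf_nmds <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f over %d restart(s)%s\n",
              ncol(x$points), x$stress, x$n_restarts,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
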