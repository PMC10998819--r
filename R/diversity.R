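# Alpha diversity and the univariate battery: Shapiro-Wilk and Levene
# prechecks, ANOVA, Tukey HSD with compact letter display.

#' Alpha diversity per sample
#'
#' Richness is the number of OTUs with a positive count; Shannon diversity
#' is computed on the sample's proportions in natural-log units, so it is
#' bounded above by log(richness).
#'
#' @param counts count matrix with positive row sums.
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("zero-sum sample(s): ", paste(rownames(counts)[rs == 0], collapse = ", "))
  }
  data.frame(sample_id = rownames(counts),
             richness = unname(rowSums(counts > 0)),
             shannon = unname(vegan::diversity(counts, index = "shannon")),
             stringsAsFactors = FALSE)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group centre (the group
#' mean by default; `center = "median"` gives the Brown-Forsythe variant).
#'
#' @param values numeric vector, or a list of numeric vectors (one per
#'   group) in which case `groups` is ignored.
#' @param groups grouping factor aligned with `values`.
#' @param center "mean" (classical Levene) or "median" (Brown-Forsythe).
#' @return list with `F` and `p`.
#' @export
levene_test <- function(values, groups = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("Levene's test needs at least two groups")
  if (any(table(g) < 2L)) stop("every group needs at least two observations")
  center_fun <- if (center == "mean") mean else stats::median
  dev <- abs(values - stats::ave(values, g, FUN = center_fun))
  if (all(dev == 0)) stop("all deviations are zero; F is undefined")
  res <- car::leveneTest(values ~ g, center = center_fun)
  list(F = unname(res$`F value`[1L]), p = unname(res$`Pr(>F)`[1L]))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard AS R94 implementation with explicit
#' domain errors (3 <= n <= 5000, non-constant input).
#'
#' @param values numeric vector.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (diff(range(values)) == 0) stop("constant input: W is undefined")
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = unname(res$p.value))
}

#' ANOVA with Tukey HSD and compact letter display
#'
#' One-way ANOVA of `values` on `groups` (or two-way with interaction when
#' `groups2` is supplied), followed by Tukey's honestly significant
#' difference test at confidence `conf`. Pairwise Tukey p-values come from
#' the studentized-range distribution; group letters are computed by
#' insert-and-absorb so that levels sharing a letter are not significantly
#' different. Normality (Shapiro-Wilk per group) and variance homogeneity
#' (Levene) prechecks are reported alongside; a precheck failure is
#' flagged, not fatal, and the ANOVA is still run.
#'
#' @param values numeric response.
#' @param groups primary factor.
#' @param groups2 optional second factor (two-way model with interaction).
#' @param conf confidence level for Tukey HSD (default 0.95).
#' @return `amf_anova`: list with `table` (per-term df, F, p), `tukey`
#'   (pairwise comparisons per factor), `letters` (per factor), and
#'   `precheck` (Shapiro-Wilk per group of the primary factor, Levene).
#' @export
anova_tukey <- function(values, groups, groups2 = NULL, conf = 0.95) {
  g1 <- factor(groups)
  if (nlevels(g1) < 2L) stop("need at least two levels")
  if (any(table(g1) < 2L)) stop("every level needs at least two observations")
  df <- data.frame(y = values, g1 = g1)
  form <- y ~ g1
  if (!is.null(groups2)) {
    df$g2 <- factor(groups2)
    form <- y ~ g1 * g2
  }
  fit <- stats::aov(form, data = df)
  tab <- summary(fit)[[1L]]
  terms_tab <- data.frame(
    term = trimws(rownames(tab))[seq_len(nrow(tab) - 1L)],
    df = tab$Df[seq_len(nrow(tab) - 1L)],
    F = tab$`F value`[seq_len(nrow(tab) - 1L)],
    p = tab$`Pr(>F)`[seq_len(nrow(tab) - 1L)],
    stringsAsFactors = FALSE)
  ms <- tab$`Mean Sq`
  if (ms[length(ms)] <= 1e-12 * max(ms, .Machine$double.xmin)) {
    stop("zero residual variance; Tukey HSD undefined")
  }

  tuk <- stats::TukeyHSD(fit, conf.level = conf)
  letters_by_term <- list()
  tukey_by_term <- list()
  for (term in names(tuk)) {
    pairs <- as.data.frame(tuk[[term]])
    pairs$pair <- rownames(pairs)
    rownames(pairs) <- NULL
    tukey_by_term[[term]] <- pairs[c("pair", "diff", "lwr", "upr", "p adj")]
    lev <- levels(interaction(df[strsplit(term, ":")[[1L]]], drop = TRUE, sep = ":"))
    if (length(strsplit(term, ":")[[1L]]) == 1L) lev <- levels(df[[term]])
    pm <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
    halves <- strsplit(pairs$pair, "-", fixed = TRUE)
    ok <- lengths(halves) == 2L
    for (i in which(ok)) {
      a <- halves[[i]][1L]; b <- halves[[i]][2L]
      if (a %in% lev && b %in% lev) pm[a, b] <- pm[b, a] <- pairs$`p adj`[i]
    }
    if (all(!is.na(pm[upper.tri(pm)]))) {
      letters_by_term[[term]] <- compact_letters(pm, alpha = 1 - conf)
    }
  }

  shapiro_by_group <- lapply(split(values, g1), function(v) {
    tryCatch(shapiro_wilk(v), error = function(e) list(W = NA_real_, p = NA_real_))
  })
  levene <- tryCatch(levene_test(values, g1),
                     error = function(e) list(F = NA_real_, p = NA_real_))
  precheck_ok <- all(vapply(shapiro_by_group, function(x) is.na(x$p) || x$p > 0.05,
                            logical(1))) && (is.na(levene$p) || levene$p > 0.05)

  structure(list(table = terms_tab, tukey = tukey_by_term,
                 letters = letters_by_term,
                 precheck = list(shapiro = shapiro_by_group, levene = levene,
                                 passed = precheck_ok),
                 conf = conf),
            class = "amf_anova")
}

#' @export
print.amf_anova <- function(x, ...) {
  cat("ANOVA (Tukey HSD at", x$conf, "confidence)\n")
  print(x$table, row.names = FALSE)
  for (term in names(x$letters)) {
    cat("letters [", term, "]: ",
        paste(names(x$letters[[term]]), x$letters[[term]], sep = "=", collapse = "  "),
        "\n", sep = "")
  }
  if (!x$precheck$passed) cat("note: normality/variance prechecks flagged\n")
  invisible(x)
}

#' Table-1-style group summary
#'
#' Formats per-group "mean +/- SD letter" strings for a response.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param digits rounding for mean and SD.
#' @param conf Tukey confidence level.
#' @return data.frame with `group`, `mean`, `sd`, `letter`, `label`.
#' @export
group_summary <- function(values, groups, digits = 2, conf = 0.95) {
  fit <- anova_tukey(values, groups, conf = conf)
  g <- factor(groups)
  mu <- tapply(values, g, mean)
  sdv <- tapply(values, g, stats::sd)
  let <- fit$letters[[1L]][levels(g)]
  data.frame(group = levels(g), mean = unname(mu), sd = unname(sdv),
             letter = unname(let),
             label = sprintf("%.*f ± %.*f %s", digits, mu, digits, sdv, let),
             stringsAsFactors = FALSE)
}
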