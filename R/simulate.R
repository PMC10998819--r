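# Dirichlet-multinomial simulator for a paired root/soil, two-site,
# bimonthly AMF amplicon survey with known per-OTU ground truth.

# Default per-site, per-month soil chemistry parameters (mean, sd) for a
# temperate conifer-plantation survey: pH (water), total carbon and total
# nitrogen (percent dry soil), total phosphorus (mg per kg soil). Site A is
# sampled in all six bimonthly months, site B in three.
default_soil_params <- function() {
  rbind(
    data.frame(site = "siteA",
               month = c("May", "July", "September", "November", "January", "March"),
               pH_mean = c(4.74, 5.02, 4.61, 5.23, 5.10, 5.43),
               pH_sd   = c(0.47, 0.24, 0.45, 0.39, 0.53, 0.37),
               TC_mean = c(10.29, 10.07, 6.29, 8.44, 9.45, 7.14),
               TC_sd   = c(4.84, 1.95, 2.57, 3.65, 3.67, 2.85),
               TN_mean = c(0.65, 0.61, 0.45, 0.55, 0.74, 0.48),
               TN_sd   = c(0.26, 0.10, 0.15, 0.19, 0.29, 0.16),
               TP_mean = c(81.43, 76.33, 59.30, 89.58, 31.33, 28.86),
               TP_sd   = c(25.03, 18.03, 18.65, 18.42, 9.40, 8.54),
               stringsAsFactors = FALSE),
    data.frame(site = "siteB",
               month = c("May", "November", "March"),
               pH_mean = c(4.78, 5.29, 5.09),
               pH_sd   = c(0.33, 0.40, 0.23),
               TC_mean = c(16.84, 17.70, 16.48),
               TC_sd   = c(3.41, 3.18, 2.01),
               TN_mean = c(1.06, 1.06, 1.01),
               TN_sd   = c(0.18, 0.15, 0.11),
               TP_mean = c(81.19, 69.19, 70.62),
               TP_sd   = c(9.85, 5.15, 6.62),
               stringsAsFactors = FALSE)
  )
}

# Yearlong mean relative abundances of the community's dominant members,
# in decreasing order: two co-dominant OTUs near 18%, then a shoulder of
# 22 OTUs between 4.6% and 0.9%.
default_dominant_props <- function() {
  c(0.184, 0.177, 0.046, 0.042, 0.038, 0.033, 0.032, 0.028,
    0.027, 0.027, 0.025, 0.023, 0.018, 0.017, 0.017, 0.015,
    0.014, 0.014, 0.012, 0.011, 0.011, 0.010, 0.010, 0.009)
}

#' Configure the community simulator
#'
#' Builds and validates the parameter set for [generate_dataset()]. The
#' defaults emulate the study design the package targets: two sites with
#' five trees each, paired root and soil samples per tree, six bimonthly
#' sampling months at site A and three (May, November, March) at site B —
#' 90 samples in total — with per-sample read depths drawn uniformly from
#' `depth_range`. The community holds `n_dominant` abundant OTUs whose
#' baseline mean proportions are `dominant_mean_props`, a long power-law
#' tail of rare OTUs, `n_seasonal` OTUs structurally absent in designated
#' months, a root-preferential OTU subset, and pH-responsive OTUs whose
#' log-abundance tracks the sample's soil pH.
#'
#' @param seed master seed; every random draw derives from it.
#' @param sites site labels.
#' @param n_trees_per_site trees (biological replicates) per site.
#' @param months sampling calendar (ordered labels).
#' @param site_months named list site -> months sampled there; default all
#'   months at the first site and months 1, 4, 6 at the second.
#' @param n_otus total OTU count in the community.
#' @param n_dominant number of designated abundant OTUs.
#' @param dominant_mean_props baseline mean proportions of the dominant
#'   OTUs (decreasing, each > 0, summing to < 1).
#' @param tail_decay power-law exponent for the rare-tail proportions
#'   (proportion of tail rank i is i^-tail_decay, renormalised).
#' @param n_seasonal number of structurally seasonal OTUs.
#' @param seasonal_absence_months named list OTU id -> months in which the
#'   OTU's proportion is forced to zero; default assigns the first
#'   `n_seasonal` tail OTUs one absence month each, cycling the calendar.
#' @param compartment_effect log-fold change added to root samples for the
#'   root-preferential OTU subset.
#' @param comp_pref_otus indices of root-preferential OTUs.
#' @param ph_slope per-unit-pH slope on log proportion for pH-responsive OTUs.
#' @param ph_otus indices of pH-responsive OTUs.
#' @param month_effects list of `list(month=, otus=, logfc=)` entries adding
#'   a month-specific log-fold shift to an OTU subset (single-month
#'   community shifts for power studies).
#' @param depth_range integer interval of per-sample read depths.
#' @param overdispersion Dirichlet concentration scalar; counts are
#'   Dirichlet-multinomial with alpha = proportions * overdispersion.
#'   `Inf` gives plain multinomial sampling.
#' @param soil_param_table per-site, per-month normal mean/sd table for
#'   pH, TC, TN, TP (see `default_soil_params()` layout).
#' @return validated `amf_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              sites = c("siteA", "siteB"),
                              n_trees_per_site = 5L,
                              months = amf_months(),
                              site_months = NULL,
                              n_otus = 700L,
                              n_dominant = 24L,
                              dominant_mean_props = default_dominant_props(),
                              tail_decay = 0.5,
                              n_seasonal = 30L,
                              seasonal_absence_months = NULL,
                              compartment_effect = 0.7,
                              comp_pref_otus = NULL,
                              ph_slope = 0.8,
                              ph_otus = 1:4,
                              month_effects = list(),
                              depth_range = c(3537L, 16435L),
                              overdispersion = 500,
                              soil_param_table = NULL) {
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  if (is.null(site_months)) {
    site_months <- stats::setNames(vector("list", length(sites)), sites)
    site_months[[1L]] <- months
    if (length(sites) >= 2L) {
      for (s in sites[-1L]) site_months[[s]] <- months[c(1L, 4L, 6L)[c(1L, 4L, 6L) <= length(months)]]
    }
  }
  if (is.null(seasonal_absence_months)) {
    if (n_seasonal > n_otus - n_dominant) stop("n_seasonal exceeds the rare tail size")
    idx <- n_dominant + seq_len(n_seasonal)
    seasonal_absence_months <- stats::setNames(
      as.list(months[((seq_len(n_seasonal) - 1L) %% length(months)) + 1L]),
      otu_ids[idx])
  }
  if (is.null(comp_pref_otus)) {
    n_pref_tail <- min(59L, max(0L, n_otus - n_dominant - n_seasonal))
    comp_pref_otus <- c(2L, n_dominant + n_seasonal + seq_len(n_pref_tail))
    comp_pref_otus <- comp_pref_otus[comp_pref_otus <= n_otus]
  }
  config <- structure(list(
    seed = as.integer(seed),
    sites = sites,
    n_trees_per_site = as.integer(n_trees_per_site),
    months = months,
    site_months = site_months,
    compartments = c("root", "soil"),
    n_otus = as.integer(n_otus),
    otu_ids = otu_ids,
    n_dominant = as.integer(n_dominant),
    dominant_mean_props = dominant_mean_props,
    tail_decay = tail_decay,
    n_seasonal = as.integer(n_seasonal),
    seasonal_absence_months = seasonal_absence_months,
    compartment_effect = compartment_effect,
    comp_pref_otus = as.integer(comp_pref_otus),
    ph_slope = ph_slope,
    ph_otus = as.integer(ph_otus),
    month_effects = month_effects,
    depth_range = as.integer(depth_range),
    overdispersion = overdispersion,
    soil_param_table = soil_param_table %||% default_soil_params()
  ), class = "amf_sim_config")
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  with(config, {
    if (length(dominant_mean_props) != n_dominant) {
      stop("dominant_mean_props must have length n_dominant")
    }
    if (any(dominant_mean_props <= 0)) stop("dominant_mean_props must be > 0")
    if (sum(dominant_mean_props) >= 1) stop("dominant_mean_props must sum to < 1")
    if (is.unsorted(rev(dominant_mean_props))) {
      stop("dominant_mean_props must be non-increasing")
    }
    if (n_dominant >= n_otus) stop("n_otus must exceed n_dominant")
    if (depth_range[1L] < 1L || depth_range[1L] > depth_range[2L]) {
      stop("depth_range must satisfy 1 <= lower <= upper")
    }
    if (!all(names(seasonal_absence_months) %in% otu_ids)) {
      stop("seasonal_absence_months keys must be existing OTU ids")
    }
    bad_m <- setdiff(unlist(seasonal_absence_months), months)
    if (length(bad_m)) stop("unknown absence month(s): ", paste(bad_m, collapse = ", "))
    dominant_ids <- otu_ids[seq_len(n_dominant)]
    overlap <- intersect(names(seasonal_absence_months), dominant_ids)
    if (length(overlap)) {
      stop("seasonal OTUs may not be dominant-designated: ",
           paste(overlap, collapse = ", "))
    }
    if (any(comp_pref_otus < 1L | comp_pref_otus > n_otus)) {
      stop("comp_pref_otus out of range")
    }
    if (any(ph_otus < 1L | ph_otus > n_otus)) stop("ph_otus out of range")
    if (!(is.infinite(overdispersion) || overdispersion > 0)) {
      stop("overdispersion must be positive (or Inf for multinomial)")
    }
    if (!all(sites %in% names(site_months))) {
      stop("site_months must name every site")
    }
    for (m in unique(unlist(site_months))) {
      absent <- vapply(seq_along(otu_ids), function(i) {
        m %in% (seasonal_absence_months[[otu_ids[i]]] %||% character(0))
      }, logical(1))
      if (sum(!absent) < 1L) {
        stop("month ", m, " has no structurally present OTU")
      }
    }
    for (s in sites) {
      spt <- soil_param_table
      for (m in site_months[[s]]) {
        if (!any(spt$site == s & spt$month == m)) {
          stop("soil_param_table missing row for ", s, " / ", m)
        }
      }
    }
  })
  invisible(config)
}

# Baseline community proportions: designated dominants followed by a
# power-law rare tail carrying the residual mass.
baseline_props <- function(config) {
  n_rare <- config$n_otus - config$n_dominant
  w <- seq_len(n_rare)^(-config$tail_decay)
  tail_mass <- 1 - sum(config$dominant_mean_props)
  p <- c(config$dominant_mean_props, tail_mass * w / sum(w))
  names(p) <- config$otu_ids
  p
}

# Reference pH per site: the mean of that site's configured monthly means.
site_reference_ph <- function(config, site) {
  spt <- config$soil_param_table
  rows <- spt$site == site & spt$month %in% config$site_months[[site]]
  mean(spt$pH_mean[rows])
}

# Expected (noise-free) proportion matrix, one row per metadata sample:
# baseline log-proportions plus compartment, pH and month effects, with
# structural zeros for seasonal OTUs in their absence months, renormalised.
expected_props_matrix <- function(config, md) {
  n <- nrow(md)
  p_otus <- config$n_otus
  lp <- matrix(log(baseline_props(config)), n, p_otus, byrow = TRUE)
  is_root <- as.character(md$compartment) == "root"
  if (config$compartment_effect != 0 && any(is_root)) {
    lp[is_root, config$comp_pref_otus] <-
      lp[is_root, config$comp_pref_otus] + config$compartment_effect
  }
  if (config$ph_slope != 0 && length(config$ph_otus)) {
    ref <- vapply(as.character(md$site), function(s) site_reference_ph(config, s),
                  numeric(1))
    delta <- config$ph_slope * (md$pH - ref)
    lp[, config$ph_otus] <- lp[, config$ph_otus] + delta
  }
  for (eff in config$month_effects) {
    rows <- as.character(md$month) == eff$month
    if (any(rows)) lp[rows, eff$otus] <- lp[rows, eff$otus] + eff$logfc
  }
  p <- exp(lp)
  # structural zeros: absence months per seasonal OTU
  for (id in names(config$seasonal_absence_months)) {
    rows <- as.character(md$month) %in% config$seasonal_absence_months[[id]]
    if (any(rows)) p[rows, match(id, config$otu_ids)] <- 0
  }
  p / rowSums(p)
}

#' Draw per-sample soil chemistry
#'
#' Each tree contributes one soil-chemistry record per sampling month,
#' drawn from the configured per-site, per-month normal parameters and
#' truncated to positive values; the record is shared by the tree's paired
#' root and soil samples (chemistry is measured on the surrounding soil).
#' Draws are keyed by (site, month, tree) sub-streams of the master seed.
#'
#' @param config an `amf_sim_config`.
#' @param metadata data.frame with `sample_id`, `site`, `tree`, `month`
#'   columns (compartment optional).
#' @return data.frame of `sample_id`, `pH`, `TC`, `TN`, `TP`.
#' @export
generate_soil_chemistry <- function(config, metadata) {
  spt <- config$soil_param_table
  key <- unique(metadata[c("site", "month", "tree")])
  vars <- c("pH", "TC", "TN", "TP")
  draws <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    s <- as.character(key$site[i]); m <- as.character(key$month[i])
    row <- which(spt$site == s & spt$month == m)
    if (!length(row)) stop("soil_param_table missing row for ", s, " / ", m)
    si <- match(s, config$sites)
    mi <- match(m, config$months)
    ti <- suppressWarnings(as.integer(gsub("\\D", "", as.character(key$tree[i]))))
    if (is.na(ti)) ti <- match(key$tree[i], unique(metadata$tree))
    sub_seed <- substream_seed(config$seed, si * 100000L + mi * 1000L + ti, stream = 2L)
    vals <- with_rng_seed(sub_seed, {
      out <- numeric(length(vars))
      for (v in seq_along(vars)) {
        mu <- spt[[paste0(vars[v], "_mean")]][row]
        sdv <- spt[[paste0(vars[v], "_sd")]][row]
        if (mu <= 0) stop("non-positive mean for ", vars[v], " at ", s, " / ", m,
                          ": truncation to positive values is undefined")
        x <- stats::rnorm(1L, mu, sdv)
        tries <- 0L
        while (x <= 0) {
          x <- stats::rnorm(1L, mu, sdv)
          tries <- tries + 1L
          if (tries > 1000L) stop("truncated-normal rejection failed for ", vars[v])
        }
        out[v] <- x
      }
      out
    })
    draws[[i]] <- vals
  }
  key_chem <- cbind(key, stats::setNames(as.data.frame(do.call(rbind, draws)), vars))
  merged <- merge(metadata[c("sample_id", "site", "month", "tree")], key_chem,
                  by = c("site", "month", "tree"), sort = FALSE)
  merged <- merged[match(metadata$sample_id, merged$sample_id), ]
  rownames(merged) <- NULL
  merged[c("sample_id", vars)]
}

#' Simulate a paired root/soil community survey
#'
#' Builds the sampling design from the configuration, draws soil chemistry
#' per tree and month, computes each sample's expected OTU proportions
#' (baseline log-proportions plus compartment, pH, and month effects, with
#' seasonal OTUs forced to structural zero in their absence months), and
#' draws counts from a Dirichlet-multinomial with the configured
#' overdispersion at a uniform random depth in `depth_range`. Identical
#' seeds give identical output.
#'
#' Ground-truth labels are derived from the expected proportions using the
#' same group-averaging scheme as the downstream classifier: `dominant` is
#' true when the expected mean relative abundance is at least 1% at every
#' site, and `dominant_clear`/`nondominant_clear` mark OTUs at least 50%
#' above/20% below that threshold, for which finite sequencing depth
#' cannot plausibly flip the call.
#'
#' @param config an `amf_sim_config` from [simulation_config()].
#' @return an `amf_dataset`: list with `counts` (integer matrix), `metadata`
#'   (design plus chemistry), `truth` (per-OTU labels), and `config`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  md <- do.call(rbind, lapply(config$sites, function(s) {
    months_s <- config$site_months[[s]]
    expand.grid(compartment = config$compartments,
                tree = seq_len(config$n_trees_per_site),
                month = months_s,
                site = s,
                stringsAsFactors = FALSE)[, c("site", "month", "tree", "compartment")]
  }))
  md$sample_id <- sprintf("%s_%s_t%02d_%s", md$site, md$month, md$tree, md$compartment)
  md <- md[c("sample_id", "site", "tree", "month", "compartment")]
  rownames(md) <- NULL

  chem <- generate_soil_chemistry(config, md)
  md <- cbind(md, chem[match(md$sample_id, chem$sample_id), c("pH", "TC", "TN", "TP")])
  md$CN <- md$TC / md$TN

  n <- nrow(md)
  counts <- matrix(0L, n, config$n_otus,
                   dimnames = list(md$sample_id, config$otu_ids))
  exp_props <- expected_props_matrix(config, md)
  dimnames(exp_props) <- list(md$sample_id, config$otu_ids)
  lo <- config$depth_range[1L]; hi <- config$depth_range[2L]
  theta <- config$overdispersion
  for (i in seq_len(n)) {
    p <- exp_props[i, ]
    counts[i, ] <- with_rng_seed(substream_seed(config$seed, i, stream = 1L), {
      depth <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      prob <- if (is.infinite(theta)) {
        p
      } else {
        g <- numeric(length(p))
        pos <- p > 0
        g[pos] <- stats::rgamma(sum(pos), shape = p[pos] * theta, rate = 1)
        if (sum(g) == 0) g[pos] <- p[pos]  # pathological all-zero gamma draw
        g / sum(g)
      }
      as.integer(stats::rmultinom(1L, depth, prob))
    })
  }

  truth <- build_truth(config, md, exp_props)
  md$month <- factor(as.character(md$month), levels = config$months, ordered = TRUE)
  md$compartment <- factor(md$compartment, levels = config$compartments)
  structure(list(counts = counts, metadata = md, truth = truth, config = config),
            class = "amf_dataset")
}

# Ground-truth labels from expected proportions, aggregated exactly as the
# dominance classifier aggregates observed data (group means, then site
# means, then the overall mean across groups).
build_truth <- function(config, md, exp_props) {
  key <- paste(md$site, md$month, md$compartment, sep = "\r")
  grp_means <- rowsum(exp_props, key) / as.vector(table(key))
  grp_site <- vapply(strsplit(rownames(grp_means), "\r", fixed = TRUE), `[`, "", 1L)
  site_means <- sapply(config$sites, function(s) {
    colMeans(grp_means[grp_site == s, , drop = FALSE])
  })
  overall <- colMeans(grp_means)
  min_site <- apply(site_means, 1L, min)
  seasonal_ids <- names(config$seasonal_absence_months)
  truth <- data.frame(
    otu_id = config$otu_ids,
    designated_dominant = seq_len(config$n_otus) <= config$n_dominant,
    dominant = min_site >= 0.01,
    dominant_clear = min_site >= 0.015,
    nondominant_clear = min_site <= 0.008,
    seasonal = config$otu_ids %in% seasonal_ids,
    ph_responsive = seq_len(config$n_otus) %in% config$ph_otus,
    root_preferential = seq_len(config$n_otus) %in% config$comp_pref_otus,
    expected_overall_mean = unname(overall),
    stringsAsFactors = FALSE
  )
  for (s in config$sites) {
    truth[[paste0("expected_mean_", s)]] <- unname(site_means[, s])
  }
  truth$absence_months <- vapply(config$otu_ids, function(id) {
    paste(config$seasonal_absence_months[[id]] %||% character(0), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  rownames(truth) <- NULL
  truth
}

#' Generate a synthetic BLAST-style taxonomy hit table
#'
#' Emits outfmt-6-style rows (`qseqid`, `sseqid`, `pident`, `qcovs`,
#' `stitle`) for each OTU in `truth`, with configurable fractions of OTUs
#' whose best hit falls below the identity/cover thresholds and of OTUs
#' whose subjects are all "uncultured Glomeromycotina". Some OTUs receive a
#' weaker secondary hit so best-hit selection is exercised.
#'
#' @param truth truth table from [generate_dataset()] (only `otu_id` used).
#' @param config an `amf_sim_config` (supplies the default seed).
#' @param fraction_below fraction of OTUs with all hits below 95/95.
#' @param fraction_uncultured fraction of OTUs with uncultured-only subjects.
#' @param seed RNG seed, default `config$seed`.
#' @return data.frame hit table.
#' @export
generate_hit_table <- function(truth, config, fraction_below = 0.05,
                               fraction_uncultured = 0.1, seed = config$seed) {
  genera <- c("Glomus", "Rhizophagus", "Dominikia", "Diversispora",
              "Septoglomus", "Microkamienskia", "Acaulospora",
              "Archaeospora", "Scutellospora", "Paraglomus")
  otus <- truth$otu_id
  with_rng_seed(substream_seed(seed, 1L, stream = 3L), {
    n <- length(otus)
    below <- stats::runif(n) < fraction_below
    uncult <- stats::runif(n) < fraction_uncultured
    two_hits <- stats::runif(n) < 0.3
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      pid1 <- if (below[i]) round(stats::runif(1, 85, 94.99), 2) else round(stats::runif(1, 95.5, 100), 2)
      cov1 <- if (below[i]) round(stats::runif(1, 85, 94.99), 2) else round(stats::runif(1, 95.5, 100), 2)
      genus <- genera[1L + (i - 1L) %% length(genera)]
      title1 <- if (uncult[i]) "uncultured Glomeromycotina" else paste(genus, "sp.")
      sid1 <- sprintf("VTX%05d", 1L + (i * 7L) %% 400L)
      out <- data.frame(qseqid = otus[i], sseqid = sid1, pident = pid1,
                        qcovs = cov1, stitle = title1, stringsAsFactors = FALSE)
      if (two_hits[i]) {
        # secondary hit strictly weaker in identity, same threshold side
        pid2 <- if (below[i]) round(stats::runif(1, 85, pid1 - 0.01), 2)
                else round(max(95, pid1 - stats::runif(1, 0.1, 0.5)), 2)
        cov2 <- if (below[i]) round(stats::runif(1, 85, 94.99), 2) else round(stats::runif(1, 95, 100), 2)
        title2 <- if (uncult[i]) "uncultured Glomeromycotina"
                  else paste(genera[1L + i %% length(genera)], "sp.")
        out <- rbind(out, data.frame(qseqid = otus[i],
                                     sseqid = sprintf("VTX%05d", 1L + (i * 11L) %% 400L),
                                     pident = pid2, qcovs = cov2, stitle = title2,
                                     stringsAsFactors = FALSE))
      }
      rows[[i]] <- out
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' @export
print.amf_dataset <- function(x, ...) {
  cat("amf_dataset:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  sites:", paste(x$config$sites, collapse = ", "),
      "| depth range:", paste(range(rowSums(x$counts)), collapse = "-"), "\n")
  invisible(x)
}
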