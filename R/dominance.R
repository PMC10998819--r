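# Dominance and persistence classification of OTUs, and the
# Kikvidze-Ohsawa deviation-minimisation co-dominance comparator.

#' Rank OTUs by group-averaged mean relative abundance
#'
#' The overall mean is the unweighted mean over all group profiles (both
#' sites; 18 groups under the full design) and per-site means are
#' unweighted means over each site's profiles. OTUs are sorted by
#' decreasing overall mean with ties broken by OTU id.
#'
#' @param profiles an `amf_group_profiles` from [group_profiles()].
#' @return data.frame with `otu_id`, `rank`, `overall_mean` and one
#'   `site_mean.<site>` column per site, ordered by rank.
#' @export
rank_otus <- function(profiles) {
  stopifnot(inherits(profiles, "amf_group_profiles"))
  prof <- profiles$profile
  if (nrow(prof) < 1L) stop("at least one group profile required")
  overall <- colMeans(prof)
  sites <- unique(profiles$groups$site)
  rec <- data.frame(otu_id = colnames(prof), overall_mean = unname(overall),
                    stringsAsFactors = FALSE)
  for (s in sites) {
    rows <- profiles$groups$site == s
    rec[[paste0("site_mean.", s)]] <-
      unname(colMeans(prof[rows, , drop = FALSE]))
  }
  ord <- order(-rec$overall_mean, rec$otu_id)
  rec <- rec[ord, ]
  rec$rank <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  rec[c("otu_id", "rank", "overall_mean", paste0("site_mean.", sites))]
}

#' Flag dominant OTUs
#'
#' An OTU is dominant when its average relative abundance is at least
#' `threshold` at every site (i.e. the minimum site mean clears the
#' threshold). Raising the threshold can only remove dominant OTUs.
#'
#' @param records output of [rank_otus()].
#' @param threshold dominance proportion, default 1%.
#' @return `records` with a logical `dominant` column added.
#' @export
classify_dominance <- function(records, threshold = 0.01) {
  site_cols <- grep("^site_mean\\.", names(records), value = TRUE)
  if (!length(site_cols)) stop("records carry no site_mean columns")
  min_site <- do.call(pmin, records[site_cols])
  records$dominant <- min_site >= threshold
  records
}

#' Classify OTU persistence per site and compartment
#'
#' Within each site x compartment, an OTU is detected in a month when it
#' has a positive count in at least one sample of that month; it is
#' `persistent` when detected in every month the site sampled, `seasonal`
#' when detected in at least one but not all months, and `absent` when
#' never detected. With `pooled = TRUE` sites are merged per compartment
#' (detection in a month counts samples from any site that sampled it),
#' giving a single label per OTU per compartment.
#'
#' @param counts count matrix.
#' @param metadata metadata covering all count rows.
#' @param pooled merge sites before classification.
#' @return data.frame with `otu_id`, (`site`,) `compartment`, `category`.
#' @export
classify_persistence <- function(counts, metadata, pooled = FALSE) {
  check_design(counts, metadata)
  md <- metadata[match(rownames(counts), metadata$sample_id), ]
  scopes <- if (pooled) list(all = rep(TRUE, nrow(md))) else {
    sites <- unique(as.character(md$site))
    stats::setNames(lapply(sites, function(s) as.character(md$site) == s), sites)
  }
  out <- list()
  for (scope_name in names(scopes)) {
    in_scope <- scopes[[scope_name]]
    months <- unique(as.character(md$month[in_scope]))
    if (!length(months)) stop("scope ", scope_name, " has zero sampled months")
    for (comp in unique(as.character(md$compartment))) {
      rows <- in_scope & as.character(md$compartment) == comp
      detected_by_month <- vapply(months, function(m) {
        sel <- rows & as.character(md$month) == m
        colSums(counts[sel, , drop = FALSE] > 0) > 0
      }, logical(ncol(counts)))
      n_detected <- rowSums(detected_by_month)
      category <- ifelse(n_detected == length(months), "persistent",
                         ifelse(n_detected > 0, "seasonal", "absent"))
      rec <- data.frame(otu_id = colnames(counts), compartment = comp,
                        category = category, stringsAsFactors = FALSE)
      if (!pooled) rec <- cbind(site = scope_name, rec, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Kikvidze-Ohsawa co-dominance number
#'
#' Scans every candidate number of co-dominants k and scores the fit of
#' the observed rank-abundance vector to an idealised community in which
#' the top k taxa share abundance equally and the rest are absent:
#' deviation(k) = sum_{i<=k} (x_i - ideal_k)^2 + sum_{i>k} x_i^2. Under the
#' default `ideal = "total"` model the equal share is of the whole
#' community (ideal_k = 1/k); under `ideal = "topk"` it is the observed
#' mass of the top k taxa divided by k. The co-dominance number is the k
#' minimising the deviation, smallest k on ties. The deviation is zero
#' exactly when the vector is k equal shares summing to one.
#'
#' @param abundances proportion vector summing to at most one (sorted
#'   internally in decreasing order).
#' @param ideal equal-share model: of the total community ("total") or of
#'   the top-k mass ("topk").
#' @return `amf_codominance`: list with `k`, `deviation_curve` (named by
#'   k), and `method`.
#' @export
kikvidze_ohsawa_k <- function(abundances, ideal = c("total", "topk")) {
  ideal <- match.arg(ideal)
  x <- as.numeric(abundances)
  if (!length(x)) stop("empty abundance vector")
  if (any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) > 1 + 1e-9) stop("abundances sum to more than 1")
  x <- sort(x, decreasing = TRUE)
  n <- length(x)
  csum <- cumsum(x)
  csq <- cumsum(x^2)
  total_sq <- csq[n]
  k_seq <- seq_len(n)
  ideal_k <- switch(ideal, total = 1 / k_seq, topk = csum / k_seq)
  # sum_{i<=k}(x_i - m)^2 = csq_k - 2 m csum_k + k m^2 ; tail = total_sq - csq_k
  dev <- (csq - 2 * ideal_k * csum + k_seq * ideal_k^2) + (total_sq - csq)
  k <- which.min(dev)  # which.min takes the smallest index on ties
  structure(list(k = k,
                 deviation_curve = stats::setNames(dev, k_seq),
                 method = paste0("equal-share-of-", ideal)),
            class = "amf_codominance")
}

#' @export
print.amf_codominance <- function(x, ...) {
  cat("Kikvidze-Ohsawa co-dominance: k =", x$k,
      "(", x$method, "model, deviation", signif(x$deviation_curve[x$k], 4), ")\n")
  invisible(x)
}
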