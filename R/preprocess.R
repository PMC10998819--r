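# OTU-table preprocessing: rarity filtering, BLAST-hit taxonomy labelling,
# relative abundances and group-averaged profiles.

#' Discard rare OTUs
#'
#' Removes OTUs with fewer than `min_total` reads summed over all samples
#' or detected (count > 0) in fewer than `min_samples` samples. Both
#' criteria are evaluated on the input table as a single conjunction, not
#' sequentially, so the result does not depend on application order. An OTU
#' with exactly `min_total` reads in `min_samples` samples is retained.
#'
#' @param counts validated count matrix (samples x OTUs).
#' @param min_total minimum total read count to keep an OTU.
#' @param min_samples minimum number of samples an OTU must be detected in.
#' @return list with `counts` (filtered matrix) and `removed`, a data.frame
#'   reporting each removed OTU's totals, prevalence and reason(s).
#' @export
filter_rare_otus <- function(counts, min_total = 10L, min_samples = 2L) {
  validate_count_table(counts)
  totals <- colSums(counts)
  prevalence <- colSums(counts > 0)
  low_total <- totals < min_total
  low_prev <- prevalence < min_samples
  drop <- low_total | low_prev
  if (all(drop)) stop("rarity filter removed every OTU")
  reason <- character(ncol(counts))
  reason[low_total] <- "low_total"
  reason[low_prev] <- "low_prevalence"
  reason[low_total & low_prev] <- "low_total;low_prevalence"
  removed <- data.frame(otu_id = colnames(counts)[drop],
                        total_reads = unname(totals[drop]),
                        n_samples_detected = unname(prevalence[drop]),
                        reason = reason[drop],
                        stringsAsFactors = FALSE)
  list(counts = counts[, !drop, drop = FALSE], removed = removed)
}

#' Assign taxonomy labels from a BLAST-style hit table
#'
#' For each OTU, hits qualifying at both `threshold`s (percent identity and
#' query cover) are considered; the best is the lexicographic maximum by
#' (identity, cover, then subject id for determinism). An OTU with no
#' qualifying hit is `unclassified`; one whose qualifying hits are all
#' titled "uncultured Glomeromycotina" is `uncultured`; otherwise it is
#' `assigned` with the genus taken from the best qualifying named hit
#' (first word of the subject title).
#'
#' @param hits data.frame from [read_hits()] or [generate_hit_table()].
#' @param otu_ids optional full OTU id vector; ids without hit rows are
#'   labelled `unclassified`.
#' @param threshold qualifying percent for both identity and cover
#'   (inclusive: values equal to the threshold qualify).
#' @return data.frame with `otu_id`, `status`, `taxon`, `best_identity`,
#'   `best_cover`.
#' @export
assign_taxonomy <- function(hits, otu_ids = NULL, threshold = 95) {
  stopifnot(all(c("qseqid", "sseqid", "pident", "qcovs", "stitle") %in% names(hits)))
  if (!is.numeric(hits$pident) || !is.numeric(hits$qcovs)) {
    stop("pident and qcovs must be numeric percents")
  }
  ids <- otu_ids %||% unique(hits$qseqid)
  label_one <- function(id) {
    h <- hits[hits$qseqid == id, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(otu_id = id, status = "unclassified", taxon = NA_character_,
                        best_identity = NA_real_, best_cover = NA_real_,
                        stringsAsFactors = FALSE))
    }
    # order all hits by (identity, cover, subject id) for deterministic bests
    h <- h[order(-h$pident, -h$qcovs, h$sseqid), , drop = FALSE]
    qual <- h$pident >= threshold & h$qcovs >= threshold
    if (!any(qual)) {
      return(data.frame(otu_id = id, status = "unclassified", taxon = NA_character_,
                        best_identity = h$pident[1L], best_cover = h$qcovs[1L],
                        stringsAsFactors = FALSE))
    }
    hq <- h[qual, , drop = FALSE]
    uncult <- hq$stitle == "uncultured Glomeromycotina"
    if (all(uncult)) {
      return(data.frame(otu_id = id, status = "uncultured", taxon = NA_character_,
                        best_identity = hq$pident[1L], best_cover = hq$qcovs[1L],
                        stringsAsFactors = FALSE))
    }
    named <- hq[!uncult, , drop = FALSE]
    taxon <- strsplit(named$stitle[1L], "\\s+")[[1L]][1L]
    data.frame(otu_id = id, status = "assigned", taxon = taxon,
               best_identity = hq$pident[1L], best_cover = hq$qcovs[1L],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(ids, label_one))
  rownames(out) <- NULL
  out
}

#' Per-sample relative abundances
#'
#' Divides each sample row by its total so rows sum to one.
#'
#' @param counts count matrix with positive row sums.
#' @return numeric composition matrix of the same shape.
#' @export
relative_abundance <- function(counts) {
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("zero-sum sample(s): ", paste(rownames(counts)[rs == 0], collapse = ", "))
  }
  counts / rs
}

#' Group-averaged composition profiles
#'
#' Averages per-sample compositions (unweighted) within each
#' site x month x compartment group. Under the full study design this
#' yields 12 profiles for a six-month site and 6 for a three-month site.
#'
#' @param composition matrix from [relative_abundance()].
#' @param metadata metadata covering every composition row.
#' @return `amf_group_profiles`: list with `groups` (site, month,
#'   compartment, n_samples) and `profile` (groups x OTUs matrix whose rows
#'   sum to one).
#' @export
group_profiles <- function(composition, metadata) {
  missing <- setdiff(metadata$sample_id, rownames(composition))
  if (length(missing)) {
    key <- metadata[metadata$sample_id %in% missing, c("site", "month", "compartment")]
    stop("group(s) with no composition rows: ",
         paste(unique(paste(key$site, key$month, key$compartment, sep = "/")),
               collapse = ", "))
  }
  md <- metadata[match(rownames(composition), metadata$sample_id), ]
  if (anyNA(md$sample_id)) {
    stop("composition rows absent from metadata: ",
         paste(rownames(composition)[is.na(md$sample_id)], collapse = ", "))
  }
  key <- paste(md$site, md$month, md$compartment, sep = "\r")
  profile <- rowsum(composition, key) / as.vector(table(key))
  parts <- strsplit(rownames(profile), "\r", fixed = TRUE)
  groups <- data.frame(site = vapply(parts, `[`, "", 1L),
                       month = vapply(parts, `[`, "", 2L),
                       compartment = vapply(parts, `[`, "", 3L),
                       n_samples = as.vector(table(key)),
                       stringsAsFactors = FALSE)
  rownames(profile) <- paste(groups$site, groups$month, groups$compartment, sep = ".")
  structure(list(groups = groups, profile = profile), class = "amf_group_profiles")
}

#' Genus-level composition
#'
#' Sums per-sample proportions within each assigned genus; OTUs labelled
#' `uncultured` or `unclassified` are kept as their own categories. Row
#' sums are preserved.
#'
#' @param composition per-sample composition matrix.
#' @param labels taxonomy table from [assign_taxonomy()] covering every OTU
#'   column.
#' @return samples x categories proportion matrix.
#' @export
genus_composition <- function(composition, labels) {
  missing <- setdiff(colnames(composition), labels$otu_id)
  if (length(missing)) {
    stop("OTUs without taxonomy label: ", paste(missing, collapse = ", "))
  }
  lab <- labels[match(colnames(composition), labels$otu_id), ]
  category <- ifelse(lab$status == "assigned", lab$taxon, lab$status)
  agg <- t(rowsum(t(composition), category))
  agg[, order(colnames(agg)), drop = FALSE]
}
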