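# Reading, writing and validating the pipeline's tabular formats.
#
# All files are UTF-8 tab-separated text without quoting; lines starting
# with '#' are treated as comments on input.

#' Canonical sampling-month order
#'
#' The bimonthly sampling calendar runs May through the following March, so
#' the year-round axis crosses the calendar-year boundary. Month factors
#' throughout the package use this order.
#'
#' @return character vector of month labels in sampling order.
#' @export
amf_months <- function() {
  c("May", "July", "September", "November", "January", "March")
}

#' Validate a sample-by-OTU count table
#'
#' A count table is an integer matrix with unique sample identifiers as row
#' names and unique OTU identifiers as column names; all counts are
#' non-negative and (unless `allow_empty_samples`) every sample has at
#' least one read.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns.
#' @param allow_empty_samples keep samples whose row sum is zero
#'   (used on intermediate tables after filtering).
#' @return the validated matrix, invisibly coerced to integer storage.
#' @export
validate_count_table <- function(counts, allow_empty_samples = FALSE) {
  if (!is.matrix(counts)) stop("count table must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table needs sample row names and OTU column names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (any(!is.finite(counts))) stop("count table contains non-finite values")
  if (any(counts < 0)) stop("count table contains negative counts")
  if (any(counts != floor(counts))) stop("count table contains non-integer counts")
  if (!allow_empty_samples && any(rowSums(counts) == 0)) {
    stop("samples with zero total reads: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a sample-by-OTU count table from TSV
#'
#' Expects a header row of OTU identifiers and sample identifiers in the
#' first column. Orientation is never guessed: pass `transpose = TRUE` if
#' the file stores OTUs as rows.
#'
#' @param path file path.
#' @param transpose set to `TRUE` when rows are OTUs and columns samples.
#' @param allow_empty_samples passed to [validate_count_table()].
#' @return integer matrix (samples x OTUs).
#' @export
read_count_table <- function(path, transpose = FALSE, allow_empty_samples = FALSE) {
  header_line <- Filter(function(l) !startsWith(l, "#"), readLines(path, n = 50L))[1L]
  header <- strsplit(header_line, "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(header[-1L])) {
    stop("duplicated OTU identifiers in header: ",
         paste(unique(header[-1L][duplicated(header[-1L])]), collapse = ", "))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("count table needs an ID column plus at least one OTU column")
  ids <- raw[[1L]]
  mat_chr <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- array(as.numeric(mat_chr), dim = dim(mat_chr)))
  bad <- which(is.na(num) | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer count '%s' at row '%s', column '%s'",
                 mat_chr[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], colnames(mat_chr)[bad[1L, 2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)
    stop(sprintf("negative count at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(mat_chr)[bad[1L, 2L]]))
  }
  counts <- num
  dimnames(counts) <- list(ids, colnames(mat_chr))
  if (transpose) counts <- t(counts)
  counts <- validate_count_table(counts, allow_empty_samples = allow_empty_samples)
  counts
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; writing then reading is lossless and
#' byte-stable for canonical tables.
#'
#' @param counts validated count matrix.
#' @param path output file path.
#' @param id_column header name for the sample-ID column.
#' @export
write_count_table <- function(counts, path, id_column = "sample_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' The metadata TSV must provide `sample_id`, `site`, `tree`, `month` and
#' `compartment` columns. `compartment` is restricted to the two-level
#' root/soil factor and `(site, tree, month, compartment)` must be unique.
#' A soil-chemistry table may be joined on `sample_id`; the C/N ratio is
#' derived as TC/TN where both are present.
#'
#' @param path metadata TSV path.
#' @param chemistry_path optional chemistry TSV (`sample_id`, `pH`, `TC`,
#'   `TN`, `TP`).
#' @param month_levels month factor order, default [amf_months()].
#' @return data.frame of sample records; `month` is an ordered factor.
#' @export
read_metadata <- function(path, chemistry_path = NULL, month_levels = amf_months()) {
  md <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(chemistry_path)) {
    chem <- read_chemistry(chemistry_path)
    missing <- setdiff(md$sample_id, chem$sample_id)
    if (length(missing)) {
      stop("samples missing from chemistry table: ", paste(missing, collapse = ", "))
    }
    md <- merge(md, chem, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  validate_metadata(md, month_levels = month_levels)
}

#' @rdname read_metadata
#' @param metadata data.frame to validate in place of a file.
#' @export
validate_metadata <- function(metadata, month_levels = amf_months()) {
  required <- c("sample_id", "site", "tree", "month", "compartment")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata")
  bad_comp <- setdiff(unique(metadata$compartment), c("root", "soil"))
  if (length(bad_comp)) {
    stop("unknown compartment level(s): ", paste(bad_comp, collapse = ", "))
  }
  bad_month <- setdiff(unique(as.character(metadata$month)), month_levels)
  if (length(bad_month)) {
    stop("month label(s) outside the sampling calendar: ",
         paste(bad_month, collapse = ", "))
  }
  key <- interaction(metadata$site, metadata$tree, metadata$month,
                     metadata$compartment, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicated (site, tree, month, compartment) design cells")
  }
  metadata$month <- factor(as.character(metadata$month),
                           levels = month_levels, ordered = TRUE)
  metadata$compartment <- factor(metadata$compartment, levels = c("root", "soil"))
  if (all(c("TC", "TN") %in% names(metadata))) {
    cn <- metadata$TC / metadata$TN
    if ("CN" %in% names(metadata)) {
      both <- !is.na(metadata$CN) & !is.na(cn)
      if (any(abs(metadata$CN[both] - cn[both]) > 1e-9)) {
        stop("CN column inconsistent with TC/TN")
      }
    }
    metadata$CN <- cn
  }
  metadata
}

#' Read a soil-chemistry table
#'
#' @param path TSV with columns `sample_id`, `pH`, `TC`, `TN`, `TP` (TC and
#'   TN in percent, TP in mg per kg soil).
#' @return data.frame; strictly positive TC/TN/TP enforced where present.
#' @export
read_chemistry <- function(path) {
  chem <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "pH", "TC", "TN", "TP")
  missing <- setdiff(required, names(chem))
  if (length(missing)) stop("chemistry table missing columns: ", paste(missing, collapse = ", "))
  for (col in c("TC", "TN", "TP")) {
    bad <- !is.na(chem[[col]]) & chem[[col]] <= 0
    if (any(bad)) {
      stop("non-positive ", col, " for sample(s): ",
           paste(chem$sample_id[bad], collapse = ", "))
    }
  }
  chem
}

#' Read a BLAST-style taxonomy hit table
#'
#' Tab-separated outfmt-6-style columns `qseqid`, `sseqid`, `pident`,
#' `qcovs`, `stitle`. A header line naming the columns is detected and
#' skipped, so both headered exports and raw BLAST output parse.
#'
#' @param path hit table path.
#' @return data.frame of hits; percent columns validated numeric in [0, 100].
#' @export
read_hits <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^\\s*qseqid\\b", first)
  hits <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                            header = has_header, stringsAsFactors = FALSE,
                            col.names = c("qseqid", "sseqid", "pident", "qcovs", "stitle"))
  for (col in c("pident", "qcovs")) {
    val <- suppressWarnings(as.numeric(hits[[col]]))
    bad <- is.na(val) & !is.na(hits[[col]])
    if (any(bad)) {
      stop(sprintf("malformed %s value '%s' for query '%s'",
                   col, hits[[col]][which(bad)[1L]], hits$qseqid[which(bad)[1L]]))
    }
    if (any(val < 0 | val > 100, na.rm = TRUE)) {
      stop(col, " outside [0, 100]")
    }
    hits[[col]] <- val
  }
  hits
}

#' Check that counts and metadata describe the same samples
#'
#' @param counts count matrix.
#' @param metadata metadata data.frame.
#' @return invisibly `TRUE`; errors report the offending sample sets.
#' @export
check_design <- function(counts, metadata) {
  orphans <- setdiff(rownames(counts), metadata$sample_id)
  if (length(orphans)) {
    stop("samples in counts absent from metadata: ",
         paste(orphans, collapse = ", "))
  }
  extra <- setdiff(metadata$sample_id, rownames(counts))
  if (length(extra)) {
    stop("metadata samples absent from counts: ", paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a simulated dataset to a directory
#'
#' Emits `counts.tsv`, `metadata.tsv`, `chemistry.tsv`, `hits.tsv` and
#' `truth.tsv` under `dir`. Output is deterministic for a given dataset, so
#' two runs from the same configuration produce byte-identical files.
#'
#' @param dataset an `amf_dataset` from [generate_dataset()].
#' @param dir output directory, created if absent.
#' @param hits optional hit table from [generate_hit_table()].
#' @return invisible character vector of written paths.
#' @export
write_dataset <- function(dataset, dir, hits = NULL) {
  stopifnot(inherits(dataset, "amf_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "counts.tsv")
  write_count_table(dataset$counts, p)
  paths <- c(paths, p)

  md <- dataset$metadata
  chem_cols <- intersect(c("pH", "TC", "TN", "CN", "TP"), names(md))
  p <- file.path(dir, "metadata.tsv")
  utils::write.table(md[c("sample_id", "site", "tree", "month", "compartment")],
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (length(chem_cols)) {
    p <- file.path(dir, "chemistry.tsv")
    utils::write.table(md[c("sample_id", setdiff(chem_cols, "CN"))], p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.tsv")
  utils::write.table(dataset$truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(hits)) {
    p <- file.path(dir, "hits.tsv")
    utils::write.table(hits, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
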