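make_counts <- function(mat, samples = NULL, otus = NULL) {
  samples <- samples %||% sprintf("s%d", seq_len(nrow(mat)))
  otus <- otus %||% sprintf("OTU%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(samples, otus)
  storage.mode(mat) <- "integer"
  mat
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rarity filter applies both criteria at the stated boundaries", {
  counts <- make_counts(rbind(
    c(3, 50, 5, 100),
    c(3, 0, 5, 100),
    c(3, 0, 0, 100)
  ), otus = c("nine_reads", "one_sample", "ten_reads", "keeper"))

  res <- filter_rare_otus(counts)
  expect_setequal(colnames(res$counts), c("ten_reads", "keeper"))
  expect_setequal(res$removed$otu_id, c("nine_reads", "one_sample"))
  expect_equal(res$removed$reason[res$removed$otu_id == "nine_reads"], "low_total")
  expect_equal(res$removed$reason[res$removed$otu_id == "one_sample"], "low_prevalence")
  # exactly 10 reads in 2 samples survives: "less than 10" discards
  expect_true("ten_reads" %in% colnames(res$counts))

  expect_error(filter_rare_otus(make_counts(rbind(c(1L, 2L), c(1L, 2L)))),
               "every OTU")
})

test_that("rarity criteria are a conjunction on the input, not sequential", {
  set.seed(31)
  for (rep in 1:5) {
    counts <- make_counts(matrix(rpois(20 * 15, 1.2), 20, 15))
    counts[, 1] <- counts[, 1] + 1L  # guard against empty result
    keep <- colSums(counts) >= 10 & colSums(counts > 0) >= 2
    res <- filter_rare_otus(counts)
    expect_identical(colnames(res$counts), colnames(counts)[keep])
    # both reported reasons are evaluated against the unfiltered table
    expect_equal(res$removed$total_reads,
                 unname(colSums(counts)[res$removed$otu_id]))
  }
})

test_that("taxonomy decision rule handles thresholds, uncultured and ties", {
  hits <- data.frame(
    qseqid = c("good", "low", "unc", "edge", "mixed", "mixed"),
    sseqid = c("VTX00166", "VTX00001", "AB0001", "VTX00002", "VTX00003", "VTX00004"),
    pident = c(99.81, 94.0, 98.0, 95.0, 99.0, 96.0),
    qcovs  = c(99.81, 99.0, 98.0, 95.0, 99.5, 97.0),
    stitle = c("Glomus sp.", "Glomus sp.", "uncultured Glomeromycotina",
               "Rhizophagus sp.", "uncultured Glomeromycotina", "Dominikia sp."),
    stringsAsFactors = FALSE)
  lab <- assign_taxonomy(hits, otu_ids = c("good", "low", "unc", "edge", "mixed", "nohit"))

  get <- function(id) lab[lab$otu_id == id, ]
  expect_equal(get("good")$status, "assigned")
  expect_equal(get("good")$taxon, "Glomus")
  expect_equal(get("good")$best_identity, 99.81)
  expect_equal(get("low")$status, "unclassified")
  expect_equal(get("unc")$status, "uncultured")
  # threshold is inclusive: 95.0/95.0 qualifies
  expect_equal(get("edge")$status, "assigned")
  # a named qualifying hit outranks uncultured-only labelling
  expect_equal(get("mixed")$status, "assigned")
  expect_equal(get("mixed")$taxon, "Dominikia")
  expect_equal(get("nohit")$status, "unclassified")
})

test_that("taxonomy assignment is invariant to hit-row order", {
  ds <- generate_dataset(tiny_config(seed = 3))
  hits <- generate_hit_table(ds$truth, ds$config, fraction_below = 0.2,
                             fraction_uncultured = 0.2)
  ref <- assign_taxonomy(hits, otu_ids = ds$truth$otu_id)
  for (s in 1:3) {
    set.seed(s)
    shuffled <- hits[sample.int(nrow(hits)), ]
    expect_identical(assign_taxonomy(shuffled, otu_ids = ds$truth$otu_id), ref)
  }
})

test_that("relative abundance normalises rows exactly", {
  counts <- make_counts(rbind(c(1, 3), c(5, 0)))
  ra <- relative_abundance(counts)
  expect_equal(ra[1, ], c(OTU1 = 0.25, OTU2 = 0.75))
  expect_equal(unname(ra[2, ]), c(1, 0))
  expect_true(all(abs(rowSums(ra) - 1) < 1e-12))

  one <- make_counts(matrix(5L, 1, 1))
  expect_equal(unname(relative_abundance(one)[1, ]), 1.0)

  zero <- make_counts(rbind(c(0, 0), c(1, 1)))
  expect_error(relative_abundance(zero), "zero-sum")
})

test_that("group profiles average compositions per site x month x compartment", {
  ra <- rbind(c(0.2, 0.8), c(0.4, 0.6), c(0.9, 0.1))
  dimnames(ra) <- list(c("a", "b", "c"), c("OTU1", "OTU2"))
  md <- data.frame(sample_id = c("a", "b", "c"),
                   site = "A", tree = 1:3,
                   month = c("May", "May", "July"),
                   compartment = "root", stringsAsFactors = FALSE)
  gp <- group_profiles(ra, md)
  expect_equal(nrow(gp$profile), 2L)
  may <- gp$profile[gp$groups$month == "May", ]
  expect_equal(unname(may), c(0.3, 0.7))
  # a single-sample group is that sample's composition
  july <- gp$profile[gp$groups$month == "July", ]
  expect_equal(unname(july), c(0.9, 0.1))
  expect_true(all(abs(rowSums(gp$profile) - 1) < 1e-9))

  md_extra <- rbind(md, data.frame(sample_id = "d", site = "A", tree = 4,
                                   month = "March", compartment = "soil"))
  expect_error(group_profiles(ra, md_extra), "A/March/soil")
})

test_that("a balanced six-month site yields 12 profiles and site results concatenate", {
  ds <- generate_dataset(simulation_config(seed = 2))
  ra <- relative_abundance(ds$counts)
  gp <- group_profiles(ra, ds$metadata)
  expect_equal(sum(gp$groups$site == "siteA"), 12L)
  expect_equal(sum(gp$groups$site == "siteB"), 6L)

  # per-site profiles equal the corresponding rows of the pooled result
  for (s in c("siteA", "siteB")) {
    sel <- ds$metadata$site == s
    gp_s <- group_profiles(ra[ds$metadata$sample_id[sel], , drop = FALSE],
                           ds$metadata[sel, ])
    pooled_rows <- gp$profile[gp$groups$site == s, ]
    expect_equal(gp_s$profile[rownames(pooled_rows), ], pooled_rows)
  }
})

test_that("genus aggregation preserves mass and keeps label categories", {
  ra <- rbind(c(0.3, 0.2, 0.4, 0.1))
  dimnames(ra) <- list("s1", c("a", "b", "c", "d"))
  labels <- data.frame(otu_id = c("a", "b", "c", "d"),
                       status = c("assigned", "assigned", "uncultured", "unclassified"),
                       taxon = c("Glomus", "Glomus", NA, NA),
                       stringsAsFactors = FALSE)
  gc <- genus_composition(ra, labels)
  expect_equal(gc[1, "Glomus"], 0.5)
  expect_equal(gc[1, "uncultured"], 0.4)
  expect_equal(gc[1, "unclassified"], 0.1)
  expect_lt(abs(sum(gc) - 1), 1e-12)

  all_unc <- data.frame(otu_id = c("a", "b", "c", "d"), status = "unclassified",
                        taxon = NA, stringsAsFactors = FALSE)
  gc2 <- genus_composition(ra, all_unc)
  expect_equal(ncol(gc2), 1L)
  expect_equal(unname(gc2[1, 1]), 1.0)

  expect_error(genus_composition(ra, labels[-1, ]), "without taxonomy label")
})
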