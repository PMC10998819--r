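# amfdyn

Year-round dynamics of arbuscular mycorrhizal fungi (AMF) communities in
paired root and soil samples.

AMF are obligate root symbionts that live simultaneously inside host roots
and in the surrounding soil, so questions about their seasonality only make
sense when both compartments of the same trees are tracked through a full
year. `amfdyn` implements the analysis pipeline for such a survey — an
OTU count table over samples indexed by *site x tree x month x compartment*,
plus per-sample soil chemistry (pH, total C, total N, C/N, total P) — for
community ecologists working with amplicon OTU tables.

## What the package computes

* **Preprocessing** — the rare-OTU discard rule (fewer than 10 reads in
  total *or* detected in only one sample), a BLAST-hit taxonomy rule
  (assign a genus only when percent identity *and* query cover are ≥ 95%,
  with "uncultured Glomeromycotina"-only hits kept as their own category),
  per-sample relative abundances, and **group profiles**: the unweighted
  mean composition over each site × month × compartment group.
* **Dominance and persistence** — OTUs are ranked by their mean relative
  abundance across all group profiles; an OTU is *dominant* when its
  average relative abundance is ≥ 1% at **every** site, and per
  compartment it is *persistent* (detected in all sampled months),
  *seasonal* (missed in ≥ 1 month) or *absent*. A Kikvidze–Ohsawa
  comparator finds the co-dominance number k by minimising
  `D(k) = Σ_{i≤k} (x_i − 1/k)² + Σ_{i>k} x_i²`
  over the descending rank-abundance vector `x`.
* **Diversity and univariate statistics** — richness and Shannon H′ (nats),
  Shapiro–Wilk and Levene prechecks, one- or two-way ANOVA with Tukey HSD
  and a compact letter display (`mean ± SD letter`, as in site/month
  summary tables).
* **Community statistics** — Bray–Curtis and (z-scored) Euclidean
  distances; PERMANOVA with sequential (Type I) partitioning, pseudo-F
  `F = (SS_term/df_term) / (SS_res/df_res)` and permutation p-values
  `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, including an exhaustive-enumeration
  mode for small n; pairwise PERMANOVA with Bonferroni adjustment; Mantel
  tests (Spearman) between community and chemistry distances; RDA with a
  permutation model test and per-OTU rank correlations against each
  environment variable; and NMDS (Kruskal stress-1, best of seeded
  restarts).
* **Simulation** — a Dirichlet-multinomial generator that emulates the
  survey design (2 sites, 5 trees per site, paired root/soil samples,
  bimonthly sampling with 6 months at one site and 3 at the other, read
  depths in the observed 3,537–16,435 range), with designated dominant,
  seasonal (structural-zero), root-preferential and pH-responsive OTUs and
  per-OTU ground-truth labels, so every downstream stage can be tested
  without any sequencing data.

## Worked example

```r
library(amfdyn)

cfg    <- simulation_config(seed = 42)   # 90-sample two-site design
survey <- generate_dataset(cfg)
ra     <- relative_abundance(survey$counts)

records <- classify_dominance(rank_otus(group_profiles(ra, survey$metadata)))
head(records, 3)
#>    otu_id rank overall_mean site_mean.siteA site_mean.siteB dominant
#> 1 OTU0002    1       0.2499          0.2499          0.2497     TRUE
#> 2 OTU0001    2       0.1790          0.1777          0.1817     TRUE
#> 3 OTU0003    3       0.0437          0.0424          0.0462     TRUE
sum(records$dominant)
#> [1] 18
kikvidze_ohsawa_k(records$overall_mean)
#> Kikvidze-Ohsawa co-dominance: k = 12 ( equal-share-of-total model, deviation 0.06888 )

bc  <- distance_matrix(ra, "bray")
permanova(bc, survey$metadata[c("site", "compartment", "month")],
          n_perm = 999, seed = 1)
#>          term df     SS      R2     F     p
#> 1        site  1 0.0314 0.00858  0.91 0.451
#> 2 compartment  1 0.5590 0.15298 16.21 0.001
#> 3       month  5 0.2363 0.06466  1.37 0.058
#> 4    Residual 82 2.8273 0.77377    NA    NA
#> 5       Total 89 3.6540 1.00000    NA    NA
```

The dominance table says the two designated co-dominant OTUs head the
ranking (the root-preferential one is boosted above its soil baseline),
18 OTUs clear the 1%-at-both-sites bar in this realisation, and the
equal-share scan places the co-dominance number at k = 12. The PERMANOVA
partition recovers the planted structure: compartment explains ~15% of the
community variance (p = 0.001) while site explains none, and the monthly
signal is marginal. A Mantel test of the soil community against soil pH at
the six-month site gives r = 0.81 (p = 0.001) under the default pH
forcing:

```r
soil_a <- survey$metadata$site == "siteA" & survey$metadata$compartment == "soil"
ids    <- survey$metadata$sample_id[soil_a]
ph     <- as.matrix(survey$metadata[soil_a, "pH", drop = FALSE]); rownames(ph) <- ids
mantel_test(distance_matrix(ra[ids, ], "bray"),
            distance_matrix(ph, "euclidean"), n_perm = 999, seed = 2)
#> Mantel test (spearman): r = 0.8071, p = 0.001 (999 permutations)
```

## Vignette

`vignettes/amfdyn-methods.Rmd` documents the statistical model behind the
simulator, the classification rules, the permutation conventions, the
numerical choices and the known limitations.
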