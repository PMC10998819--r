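Package: amfdyn
Title: Year-Round Root and Soil Arbuscular Mycorrhizal Fungi Community Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing year-round paired root and soil arbuscular
    mycorrhizal fungi (AMF) amplicon surveys. Implements rare-OTU filtering
    and BLAST-hit taxonomy labelling rules, group-averaged relative-abundance
    profiles, a dominance/persistence classification of OTUs with a
    Kikvidze-Ohsawa co-dominance comparator, alpha diversity with
    ANOVA/Tukey compact letter displays, and permutation-based community
    statistics (PERMANOVA with pairwise contrasts, Mantel tests, redundancy
    analysis with per-OTU environment correlations, and NMDS ordination).
    Ships a Dirichlet-multinomial community simulator that emulates a
    two-site, bimonthly, paired-compartment sampling design with known
    ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
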