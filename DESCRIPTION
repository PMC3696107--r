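Package: meningsub
Title: Molecular Subgrouping of Benign Meningioma from Metabolic,
    Cytogenetic and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for rule-based molecular subgrouping of
    histologically benign (WHO grade I) meningioma into benignA and
    benignB subgroups, combining NMR metabolite quantification by
    Lorentzian peak fitting, FISH deletion calling from nuclei signal
    counts, two-group differential expression with a combined
    fold-change / p-value / Benjamini-Hochberg FDR filter, unsupervised
    hierarchical clustering, exact two-tailed Fisher association of
    subgroup with four-year recurrence, and delta-delta-Ct relative
    quantification with an exact Mann-Whitney test. Includes a seeded
    synthetic-cohort generator (metabolite spectra, FISH counts,
    expression matrices with planted effects, Ct tables) so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
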