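Package: promlab
Title: Design and Analysis of Synthetic Core Promoter Reporter Experiments
Version: 0.1.0
Authors@R:
    person("promlab", "developers", email = "promlab@example.org", role = c("aut", "cre"))
Description: Tools for structure-function analysis of metazoan core promoters:
    position weight matrix models of core promoter elements with
    mutual-information optimized score thresholds, TSS tag-cluster calling and
    MAD peakedness scoring, promoter architecture classification, binding-site
    conservation scoring against sampled substitution nulls, a synthetic
    promoter mutation design engine (knockouts, consensus replacement,
    strength series, point mutations, substitutions, positional shifts,
    context exchange, combinatorial libraries), dual-luciferase plate
    normalization with outlier QC, motif effect and log-additivity analytics,
    expression-based activity logos, and additive/linear models of promoter
    activity. Includes seeded generators of synthetic datasets with planted
    ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
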