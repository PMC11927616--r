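Package: fixsearch
Title: Fixation-Aligned Analysis of Visual Feature Coding and Attention in
    Primate Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how visual-feature (axis) coding interacts
    with attentional modulation in fixation-aligned spike and local field
    potential recordings from a free-gaze visual search task. Detects
    axis-coding units with partial-least-squares encoding models and a
    split-and-permute significance procedure, computes category selectivity
    and attention indices, characterises population representational
    geometry (dissimilarity matrices, pairwise distances and angles),
    estimates fixation-windowed spike-LFP coherence with condition sample
    equalisation, and measures frequency-domain Granger causality from
    bivariate vector autoregressions. Includes a synthetic-session simulator
    with planted ground truth (category-structured stimulus features,
    axis-coding units, attentional gain, theta-band spike-field coupling) so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
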