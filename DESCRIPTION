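Package: stallflow
Title: Capillary Stall Detection, Crowd-Sourced Scoring, and Cortical Blood
    Flow Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying non-flowing ("stalled") cortical
    capillaries and cerebral blood flow from in vivo two-photon imaging
    experiments in mice. Provides a synthetic-data generator for vascular
    networks, time-lapse image stacks, line-scan velocimetry images,
    annotator pools and behavioral event logs with known ground truth; 3-D
    vessel centerline extraction and capillary segment identification; a
    crowd-sourced scoring engine with gold-standard sensitivity calibration,
    accuracy-weighted vote aggregation, a sensitivity-sum stopping rule,
    base-rate control and expert triage; Radon-style line-scan red blood
    cell velocimetry, vessel diameter and volumetric flow measurement;
    stall prevalence and cellular composition summaries; tiered arithmetic
    and linear network models of the cerebral blood flow deficit caused by
    capillary occlusions; and behavioral scoring (Y-maze spontaneous
    alternation, object replacement preference, three-chamber sociability,
    balance beam) with normality-gated group comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    tiff,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
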