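Package: spikescore
Title: Ground-Truth Evaluation of Spike Sorting Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores automated spike-sorting outputs against ground truth using
    tolerance-window spike-train matching and per-unit accuracy, precision and
    recall; computes per-unit quality metrics (bandpass-filtered SNR with a
    robust MAD noise estimate, firing rate, and the inter-spike-interval
    violation ratio); aggregates results into sorter-by-study tables with
    SNR thresholding and linear-regression imputation of missing runs; and
    generates synthetic ground-truth recordings and controlled pseudo-sortings
    so the whole evaluation stack is testable without external data. Reads and
    writes the MDA binary array format, JSON manifests and SHA-1 content URIs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
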