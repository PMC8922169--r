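Package: ohcompliance
Title: Compliance Testing Strategies for Occupational Exposure Limits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements and compares three strategies for testing compliance
    of similar exposure groups (SEGs) with occupational exposure limits:
    the EN689:1995 preliminary and statistical tests (lognormal 5%
    exceedance), the EN689:2018 preliminary and statistical tests (upper
    tolerance limit of the 95th percentile at 70% confidence), and the
    BOHS-NVvA individual compliance test based on a random-effects
    decomposition of log exposures into between- and within-worker
    variance components. Includes a synthetic similar-exposure-group
    generator with lognormal between-/within-worker structure, CSV input
    and output of full-shift personal exposure measurements, and a
    reporting pipeline that tallies compliance, uncertain-compliance and
    non-compliance decisions per strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
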