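Package: perioscan
Title: A-Tract Spacing Periodicity in Prokaryotic Genome Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of DNA curvature-related A-tract
    spacing periodicity in nucleotide sequences. Implements the whole-sequence
    periodicity plot (spacing histogram of AA/TT dinucleotide tracts,
    normalization against the random-placement expectation, 3-bp smoothing,
    parabolic detrending, and a direct-summation Fourier spectrum on a fine
    period grid) with the MaxQ/PMaxQ and MaxQ*/PMaxQ* indices; a sliding-window
    periodicity scan with the Max2, Max3 and MaxMax persistency indices and
    greyscale heatmap export; cohort-level statistics relating persistent
    periodicity to prophage presence (Fisher's exact test, Mann-Whitney U,
    one-strain-per-species resampling); and seeded synthetic-sequence
    generators (i.i.d. backgrounds, planted periodicity with real-valued
    periods, labelled cohorts) for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
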