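Package: threadscan
Title: Translation Scanning and mRNA Threading Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Threadscan", "Developers", email = "maintainer@threadscan.dev",
           role = c("aut", "cre"))
Description: Analysis pipeline for studies of mRNA threading through the
    ES6S region of the 40S ribosomal subunit and its consequences for
    translation initiation. Implements reverse-transcriptase termination
    site (RT-stop) crosslink mapping on 18S rRNA with helix annotation;
    spike-in median-of-ratios normalization, translation-efficiency (TE)
    quantification and classification from monosomal/polysomal
    polysome-profiling counts; 5' UTR feature extraction (length, GC,
    G-quadruplex and (GGC/A)n motif scanning, Nussinov structure proxy,
    TOP flagging) with Mann-Whitney and chi-square group statistics and
    feature PCA; full-translation-time (FTT) estimation from continuous
    luciferase recordings plus Chou-Talalay median-effect combination
    index; a solvent-side mRNA path model and oligo-rRNA duplex mapping;
    and seeded synthetic-data generators for every input with ground-truth
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
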