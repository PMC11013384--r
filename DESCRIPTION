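Package: crisprkit
Title: Sequencing-Based and Biophysical Characterization of CRISPR-Cas
    Effectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for the computational layer of CRISPR-Cas
    effector characterization: PAM determination from randomized-library
    protection/cleavage sequencing (enrichment scoring, fold-change
    filtering, sequence-logo matrices, adapter-junction cleavage scans),
    mature crRNA boundary mapping from small RNA-seq read pairs,
    plasmid-interference and phage-plaque fold-change statistics with the
    zero-plaque rule, bio-layer interferometry dissociation kinetics,
    magnetic-tweezers rotation-curve shifts and R-loop sizing, and a
    minimal substitution-only quantifier for amplicon base-editing reads.
    Every input can be generated by a seedable synthetic-data module that
    plants a ground-truth manifest, so the full pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
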