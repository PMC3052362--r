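Package: usvrep
Title: Developmental Analysis and Synthesis of Mouse Ultrasonic Vocal Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the development of rodent ultrasonic
    vocalization (USV) repertoires from syllable annotation tables:
    rule-based classification of syllables into the eleven canonical
    CBA/CaJ syllable types, data-driven bout segmentation from
    inter-syllable intervals, repertoire statistics (Zipf rank-frequency
    slopes, syllable-pair contingency tests, switching probabilities,
    audibility and spectral-purity censuses), and zeroth- through
    fourth-order sequence entropy with chi-squared comparisons between
    entropic levels and between age groups.  Also provides a "virtual
    mouse vocal organ": age-calibrated Markov generation of syllable
    sequences with parametric frequency-modulated waveform synthesis to
    WAV, and a calibrated synthetic-repertoire generator so that every
    stage of the pipeline can be exercised and validated without
    original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
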