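Package: poincaregrid
Title: Beat-to-Beat RR-Interval Analytics for Sinus Node Dysfunction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing beat-to-beat RR-interval series from
    24-hour ambulatory (Holter) electrocardiography in dogs, aimed at
    differentiating sinus node dysfunction caused by sinoatrial exit block
    from the bradycardia of high-parasympathetic/low-sympathetic autonomic
    modulation. Provides heart-rate, sinus-pause and rate-corrected RMSSD
    metrics with automatic stable/sleep-hour selection; quantification of
    Poincare-plot cluster geometry; a three-dimensional beat-interval
    density-grid classifier over 60 ms cubic cells; a shallow neural-network
    classifier over multiple-frequency sine mappings of interval triples;
    and a stochastic sinoatrial exit-block simulator that generates labelled
    synthetic rhythms for the three diagnostic classes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
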