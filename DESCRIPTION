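Package: syllseq
Title: Spiking Basal Ganglia Model of Syllable Sequencing Under Dopamine
    Depletion and Pallidal/Subthalamic Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and simulates a cortico-basal-ganglia-thalamus-cortex
    spiking neural model of a syllable repetition (diadochokinesia) task using
    the Neural Engineering Framework: leaky integrate-and-fire ensembles,
    least-squares decoders, and semantic-pointer buffers routed by a
    Gurney-style action-selection circuit with separately implemented GPi and
    SNr output nuclei. Striatal dopamine (D1/D2 gains) and the afferent
    weights of the subthalamic nucleus and globus pallidus internus are
    tunable, so that Parkinsonian sequencing degradation and its compensation
    by STN or GPi inhibition can be simulated. Includes the full analysis
    pipeline: motor-pulse extraction, correct-syllable counting, a
    four-category error taxonomy, pulse-shape classification, parameter-sweep
    tables with stability regions, and the associated statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
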