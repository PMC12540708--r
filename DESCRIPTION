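Package: jnkdyn
Title: Modeling and Analysis of JNK Signaling Dynamics and Target Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the temporal dynamics of c-Jun N-terminal
    kinase (JNK) activity shape downstream gene expression. Provides a
    seven-species ordinary differential equation model of the
    JNK -> phospho-c-Jun -> target-gene axis with DUSP1 negative feedback,
    driven by sustained, transient or pulsed step stimuli, with mass-action,
    Hill-promoter and transcription-delay variants; Saltelli-sampled Sobol
    global sensitivity analysis of target-gene output; grid-scan RMSE fitting
    of mRNA decay rates, promoter affinities and transcriptional delays to
    scaled time-course expression profiles with half-life prediction;
    quantification of single-cell kinase-translocation-reporter traces
    (baseline, pulse counting, activity durations); filtering, scaling and
    k-means clustering of differential-expression time courses with cluster
    overlap and half-life cross-referencing; and synthetic-data generators
    with known ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
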