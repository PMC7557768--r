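Package: ppntract
Title: Probabilistic Tractography and Topography of Pallidotegmental Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs and quantifies structural connectivity between the
    pedunculopontine nucleus (PPN) and the internal and external pallidal
    segments (GPi, GPe). Provides probabilistic streamline tractography over
    discrete fiber-orientation fields, seed/include/exclude bundle selection,
    track-density mapping, group maximum-probability maps, percentage-overlap
    topography against pallidal functional territories, and paired
    Wilcoxon signed-rank comparisons of streamline counts, together with a
    fully ground-truthed synthetic phantom cohort generator for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
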