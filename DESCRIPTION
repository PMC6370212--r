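Package: anthoNet
Title: Anthocyanin MS/MS Annotation, Relative Quantification and
    Transcript-Metabolite Correlation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying decorated anthocyanins from positive-mode
    tandem mass spectra by exact monoisotopic mass arithmetic over an
    aglycone/glycosyl/acyl building-block library, explaining fragment ions as
    neutral residue losses, applying the E440/Emax UV glycosylation rule,
    quantifying metabolites relative to an internal standard across flower
    developmental stages, deriving transcript levels from qRT-PCR standard
    curves with housekeeping normalization, and integrating transcripts and
    metabolites through Pearson correlation networks summarized by node
    strength and network strength. Includes a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'spectrum.R'
    'blockLibrary.R'
    'annotate.R'
    'anthoNet-package.R'
    'expression.R'
    'formula.R'
    'netstat.R'
    'quantify.R'
    'pipeline.R'
    'synth.R'
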