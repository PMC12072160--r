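Package: secretofft
Title: Secretome Differential Analysis and 2D-FFT Quantification of
    Cytoskeleton Fiber Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free secretome profiling of hormone-stimulated
    granulosa cells and for spectral quantification of F-actin organization in
    fluorescence images. The proteomics track covers top-3 precursor-area
    quantification, unique-peptide filtering, Venn partitioning of
    identification lists, quantile normalization, log2 fold-change calling,
    Z-score clustergrams and local hypergeometric pathway over-representation
    with false-discovery-rate control. The imaging track measures per-ROI
    fluorescence intensity, angular spectral anisotropy (amplitude) and
    spectral eccentricity from 2D Fast Fourier Transforms, with one-way ANOVA,
    Bonferroni post hoc comparisons and median confidence intervals for group
    analysis. Synthetic generators for peptide-level abundance tables and
    oriented-filament images make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    ape,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
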