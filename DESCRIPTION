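Package: octacrmb
Title: Computational Retinal Microvascular Biomarkers from OCTA Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Knowledge-driven quantification of en-face optical coherence
    tomography angiography (OCTA) images of the macula. Extracts the digital
    vasculature map from superficial and deep capillary plexus angiograms,
    applies an ETDRS fovea/parafovea grid, separates retinal large vessels
    from capillaries, and computes twelve computational retinal microvascular
    biomarkers: perfusion densities (PDL, PDCS, PDCD), box-counting fractal
    dimensions (FDS, FDD), vessel tortuosity (MVT), diameter (MVDiam) and
    dispersion (MVDisp), and ray-cast foveal avascular zone area and
    acircularity (FAS, FAD, FACS, FACD). Includes a ground-truthed synthetic
    angiogram simulator for validation, and the cohort statistics layer used
    in case-control studies: Kendall correlation structure with hierarchical
    clustering, Welch group tests with Benjamini-Hochberg control, LASSO
    biomarker models, and demographics-table statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    glmnet,
    jsonlite,
    png,
    tiff,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
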