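Package: phantomics
Title: Activity-Painting PET Phantom Simulation and Radiomics Robustness
    Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a multicentric PET radiomics robustness experiment
    end to end: heterogeneous lesions are "activity painted" by a virtual
    22Na point source moving through a 5x5x5 cm painting volume inside a
    water tank with decaying 18F background, rendered through eight imaging
    settings (voxel size, point-spread function, post-filter and noise
    surrogates for distinct PET/CT scanner reconstructions), segmented,
    discretized with fixed-bin-size and fixed-bin-number schemes, and
    summarised by 46 radiomic indices (conventional SUV statistics, shape,
    histogram, and GLCM/GLRLM/NGLDM/GLZLM texture families). Robustness of
    each index across settings is quantified by relative differences,
    inter-setting coefficients of variation, two-way mixed-effects
    absolute-agreement intraclass correlation, and Wilcoxon rank-sum tests
    with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
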