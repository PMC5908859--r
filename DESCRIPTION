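Package: algaecyto
Title: Microscopic Cytometry of Microalgae from Dual-Channel Epi-Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised single-cell cytometry for microalgal cultures from
    paired epi-fluorescence images. Chlorophyll autofluorescence is used as
    the trigger signal to detect cells (contrast enhancement, between-class
    variance threshold optimization, small-object removal, connected-component
    labeling); per-cell size, chlorophyll and Nile-Red neutral-lipid amounts
    and densities are then read out from the unmodified raw channels.
    Population-structure analytics cover relative scaling (RCS, RCCA, RCLA,
    RCCD, RCLD), Spearman rank correlations, cell-to-cell heterogeneity, and
    baseline-anchored fold-change transition states across a time course.
    Includes a ground-truthed synthetic scene and population generator so the
    whole pipeline is testable without microscope data, and a command-line
    front-end (process / analyze / simulate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
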