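Package: rowprompt
Title: Point-Prompt Engineering for Individual Tree Segmentation in Orchard Rows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to segment individual trees in dense orchard-row images by
    prompt engineering: split a semantic trunk mask into trunk instances with
    density-based clustering, fit a shared-tilt regression axis per trunk,
    derive a five-point diamond prompt (trunk bottom, summit, centre and two
    lateral points) per tree, feed the prompts to a pluggable prompt-conditioned
    segmentation backend, and score the resulting instance masks with the
    Dice-Sorensen coefficient, signed mean error, precision/recall, Dice-matched
    average precision and paired t comparisons. A synthetic orchard-scene
    generator with pixel-perfect ground truth makes every stage testable
    offline, without trained detector weights or foundation-model checkpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
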