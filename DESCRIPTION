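Package: strabmetric
Title: Quantitative Strabismus Measurement from Nine-Gaze Eye Photographs
Version: 0.1.0
Authors@R: person("strabmetric", "developers", email = "dev@strabmetric.invalid",
    role = c("aut", "cre"))
Description: Measures ocular deviation from photographs of the nine cardinal
    gaze positions. Given per-gaze sclera and limbus segmentation masks (from
    any pluggable segmenter), the package registers all gazes onto the primary
    gaze via a similarity transform anchored on the innermost sclera points,
    models the limbus and sclera as circles, locates the corneal light reflex
    in the primary gaze, recovers the limbus center in eccentric gazes by
    ellipse fitting and short-axis extension, and reports pixel-wise deviation
    distances and impaired-versus-normal movement percentages. A synthetic
    nine-gaze eye renderer with exhaustive ground truth supports end-to-end
    validation, including cranial-nerve-palsy presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
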