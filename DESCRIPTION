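Package: mycocolor
Title: Image-Based Color Identification of Fungal Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the color of background-masked fungal photographs and
    names it against a Rayner-style mycological reference chart. Images are
    loaded as pixel arrays, chroma-key (bright green) or alpha backgrounds are
    removed, the remaining pixels are binned into a normalized eight-bin
    histogram in either the CIELAB or sRGB color space, and each bin's
    representative color is matched to the nearest reference entry by
    Euclidean or Chi-square distance. Results report color names, hue groups,
    and the fungal pigment classes associated with each hue. Also provides
    validation machinery for benchmarking such tools: multiclass hue
    confusion matrices, one-vs-rest accuracy, Cohen's kappa with banded
    interpretation, and replicate summaries, plus a synthetic swatch-image
    generator so the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jpeg,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
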