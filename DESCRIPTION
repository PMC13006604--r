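Package: virtualstain
Title: Virtual Brightfield Staining of Multiplex Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts multi-channel (multiplex) microscopy images such as
    imaging mass cytometry or multiplex immunofluorescence into virtual
    brightfield images (H&E, IHC and custom special stains) using a
    physics-based light-absorption stain model. Includes lexicon- and
    LLM-assisted mapping of marker channels to stain classes with a
    consensus agreement statistic, classical enhancement filters (median,
    unsharp masking, contrast-limited adaptive histogram equalization,
    spline resampling), a degradation simulator for building image
    restoration training pairs, paired image-quality metrics, an
    enhancement-efficiency index, OME-TIFF input/output, and a seeded
    synthetic multiplex fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    generics,
    tibble,
    yaml,
    jsonlite,
    tiff,
    xml2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
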