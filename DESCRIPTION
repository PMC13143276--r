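Package: eyecost
Title: Cost-Benefit Analysis of Compound and Simple Eye Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the competition between optics and photoreceptor arrays
    for the resources invested in an eye. Computes specific-volume costs of
    apposition (neural-superposition and fused-rhabdom) and simple eyes,
    including a metabolic energy surcharge for phototransduction, and the
    spatio-temporal Shannon information capacity of the photoreceptor array
    under natural-scene statistics, diffraction-limited optics, microvillus
    saturation and hexagonal sampling. Searches the fixed-cost morphospace of
    lens diameter and rhabdom(ere) length for configurations that maximise
    information capacity, and decomposes published insect eye measurements
    into optics and photoreceptor-array investments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
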