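Package: fallcnn
Title: Fall Detection from Waist-Worn Accelerometer Traces with a 1-D
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates falls from activities of daily living (ADLs) in
    triaxial accelerometer recordings. Traces are reduced to a fixed-duration
    observation window centered on the peak of the acceleration magnitude
    (signal magnitude vector), in either a magnitude or a triaxial variant,
    and classified by a four-block one-dimensional convolutional neural
    network trained with stochastic gradient descent with momentum and
    early stopping. Includes declarative manifest-based readers for
    heterogeneous public fall repositories, a labeled synthetic trace
    generator, stratified train/validation/test splitting,
    sensitivity/specificity/accuracy evaluation, and a per-dataset
    benchmark grid over window sizes and input variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
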