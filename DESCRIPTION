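Package: pentrack
Title: Multi-Object Tracking of Group-Housed Pigs with a Population-Capped DeepSORT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection-to-track association for overhead video of group-housed
    pigs. Implements the Shape-IoU bounding-box regression loss family, the
    forward pass of the convolutional block attention module (CBAM), and an
    improved DeepSORT tracker whose track creation is capped by a rolling
    estimate of the pen population, together with CLEAR-MOT and IDF1
    evaluation, MOTChallenge-format readers and writers, a synthetic pen
    simulator with four behavior states (stand, lie, eat, attack), and a
    command-line interface for running simulate/track/evaluate pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
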