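Package: biomotion
Title: Generative Neural Modelling of Biological Motion Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns visuo-proprioceptive biological-motion patterns from
    self-observation with a three-stage generative neural network:
    normalized directional-velocity preprocessing with self-supervised
    Euler-angle perspective-taking, direction-selective population coding
    with a global unit-norm budget, and growing Cauchy-noise competitive
    clustering with lateral probabilistic sequence learning. Recognizes
    learned motions under affine transformations, adopts unknown visual
    perspectives by predictive-coding gradient descent on rotation angles,
    simulates learned motion sequences without input, and infers
    unobservable proprioceptive features from vision alone. Includes a
    synthetic articulated-gait generator, readers and writers for TRC, C3D
    and a plain tabular motion format, and desk-scale reproductions of the
    reference experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
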