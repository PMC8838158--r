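Package: ecgcnn
Title: Six-Class ECG Beat Classification with a 297-Parameter CNN and a
    Bit-Accurate Fixed-Point Datapath Simulator
Version: 0.1.0
Authors@R:
    person("ECG CNN", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Implements a compact convolutional neural network (297
    trainable weights, no biases) that classifies single ECG heart beats
    into six classes (normal, LBBB, RBBB, PVC, APB, paced), together with
    a bit-accurate behavioural simulator of a resource-shared hardware
    datapath for the same network: a seven-lane multiply-accumulate
    processing element, ReLU, max-pooling, softmax/argmax and a
    54-register control buffer driven by a per-layer multiplexer
    schedule. Includes mini-batch gradient-descent training with
    backpropagation, a seeded synthetic ECG beat generator with
    class-distinct P-QRS-T morphology at 360 Hz, Q-format fixed-point
    quantization with saturating round-to-nearest-even arithmetic,
    confusion-matrix evaluation, a minimal WFDB reader for MIT-BIH style
    records, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
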