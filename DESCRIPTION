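Package: lifmap
Title: Linear Leaky Integrate-and-Fire Neurons and Their Exact Mapping to ReLU Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates leaky integrate-and-fire (LIF) neurons with a linear
    (soft, reset-by-subtraction) or reset-to-zero spike reset, rate-encodes
    real-valued inputs into periodic spike trains, and converts rectified
    linear (ReLU) artificial neural networks into spiking networks through an
    exact parameter mapping: connection weights pass through unchanged, the
    activation slope maps to the inverse of threshold times membrane
    capacitance, and a non-positive bias maps to the leak conductance. Spiking
    dense, 2-D convolution and max-pooling layers propagate spike trains
    through converted networks, and an equivalence-metrics suite (Pearson
    correlation matrices, confusion/agreement statistics, and coding-time
    frequency-error bounds) quantifies how closely the spiking network
    reproduces its artificial counterpart. Seeded fixture generators provide
    random networks, synthetic images and a separable two-class dataset for
    end-to-end verification without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
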