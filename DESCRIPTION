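Package: famdyn
Title: Familiarity-Induced Sharpening of Visual Response Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rate-network models of inferior temporal cortex in which
    experience-dependent synaptic plasticity interacts with firing-rate
    adaptation to sharpen visual response dynamics. Provides simulators for
    the full network with adaptation or short-term synaptic depression, the
    reduced mean-field systems (including global-inhibition and two-population
    competition variants), closed-form regime analysis of the damped
    oscillation, and an inference pipeline that recovers the post-synaptic
    dependence of recurrent and feedforward plasticity from rank-ordered
    response time courses, together with a synthetic-data generator emulating
    passive-viewing recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
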