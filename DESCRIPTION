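Package: wtabright
Title: Stochastic Winner-Take-All Spiking Network Model of Brightness Perception
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-layer k-winner-take-all spiking network in which
    Difference-of-Gaussians afferents encode grayscale images, a recurrent
    excitatory/inhibitory second layer generates stochastic spiking responses,
    reward-modulated Hebbian plasticity (an online expectation-maximization
    variant with discounted eligibility traces) shapes the plastic weights,
    and an unsupervised energy-distance classifier identifies stimuli.
    Includes parametric generators for simultaneous-brightness-contrast and
    distractor stimuli, an image-reconstruction readout of perceived
    brightness, and contextual-modulation statistics (CMI histograms,
    zero-lag cross-correlation differences, firing-rate maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
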