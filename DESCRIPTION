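Package: waveseg
Title: Retinal Wave Spike-Train Analysis and Eye-Specific Segregation
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dark-condition retinal wave recordings on
    multielectrode arrays and for eye-specific retinogeniculate segregation.
    Provides multi-channel artifact rejection, invalid-unit flagging,
    Poisson-surprise burst detection with duration and recording-edge
    exclusions, classification of wave-associated bursts via a ten-bin
    association rule on the electrode neighbourhood, per-unit and per-retina
    spiking-property summaries, spike time tiling coefficients summarised as
    median-versus-interelectrode-distance curves, percent-overlap and
    R-value-distribution quantification of two-channel dLGN section images,
    medio-lateral density reconstruction of retinocollicular innervation, and
    Welch t-tests with Holm-Bonferroni familywise control. Synthetic
    generators for wave-bearing spike trains and two-channel section stacks
    with programmed ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
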