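Package: tectoquant
Title: Quantification of Dendritic Arbors, Synaptic Puncta, and Retinotopic
    Maps in the Developing Optic Tectum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of the image-quantification pipelines
    used to study structural and functional refinement of Xenopus optic
    tectal neurons: static dendritic arbor morphometry (total length, branch
    tips, Sholl profiles, maturity classification), short-interval time-lapse
    dynamics of terminal dendritic processes (filopodia and branches;
    additions, losses, elongations, retractions, motility, density),
    two-channel synaptic-puncta colocalization counting with rolling-ball
    background subtraction, median filtering, moment-preserving and
    maximum-entropy auto-thresholding and particle size filtering, and
    calcium-imaging retinotopic grid mapping with a receptive-field sharpness
    statistic. Every pipeline is exercisable on synthetic data with known
    ground truth generated by the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
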