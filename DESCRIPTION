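Package: capcount
Title: Automated White Blood Cell Event Counting in Nailfold Capillary Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated counting of white blood cell (WBC) events that
    appear as bright moving visual gaps in nailfold capillary video. The
    pipeline equalizes frame histograms, segments capillaries by a red-dominance
    color score or a compact U-Net semantic segmenter, stabilizes frames against
    camera jitter by Fourier cross-correlation registration on the capillary
    labels with periodic reference updates, derives ordered internal, external
    and intermediate sampling coordinates from a binary ensemble mask, assembles
    a spatiotemporal (kymograph) map per capillary, and counts events as lines
    in the enhanced map via the Radon transform with local-maxima detection and
    crossing-based duplicate elimination. Includes a ground-truthed synthetic
    capillary video generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
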