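Package: huntmove
Title: Movement Responses of GPS-Collared Ungulates to Drive Hunts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies immediate and delayed movement responses of
    GPS-collared large herbivores to drive hunts. Provides trajectory
    metrics (maximum speed, mean-cosine sinuosity, cumulative and net
    displacement), detection and flee/stay classification of hunting
    events against hunted-area polygons, an isopleth-weighted
    site-familiarity index built on fixed-kernel utilization
    distributions, censored return-time construction with Kaplan-Meier
    estimation, and mixed-effects models of the distance and
    return-time responses. A synthetic herd-and-hunt generator with
    ground-truth labels allows every stage to be exercised and
    validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    survival,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
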