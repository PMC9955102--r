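Package: icpentropy
Title: Ordinal-Pattern Complexity Analysis of Intracranial Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the injured brain from the intracranial
    pressure (ICP) waveform alone. Implements Bandt-Pompe ordinal
    symbolization, normalized permutation entropy and missing (forbidden)
    ordinal-pattern counting; sliding-window complexity tracks over
    monitor-export CSV recordings; Butterworth preprocessing (powerline
    notch and low-pass); windowed intracranial compliance estimation
    (dVolume/dICP); a three-stage rule classifier separating injury-free,
    intermediate and terminal regimes; and a synthetic generator of
    pulsatile ICP recordings with balloon-driven reversible hypertension
    episodes and a terminal high-pressure stage for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
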