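Package: pamtonic
Title: Tonic Posterior Auricular Muscle EMG Analysis for Dichotic Listening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studies of tonic posterior
    auricular muscle (PAM) surface-EMG activity during dichotic selective
    listening. Generates randomized dichotic oddball stimulus sequences (tone
    bursts versus frequency-rising chirps), simulates two-muscle unipolar EMG
    recordings with known ground truth (attention-dependent tonic gain,
    exponential within-trial decay, stimulus-locked biphasic reflexes,
    power-line contamination, artifact bursts), and implements the full
    analysis chain: bipolar derivation, resampling, comb-notch and zero-phase
    band-pass filtering, stimulus-locked epoching with SNR-based artifact
    rejection, split-half reliability certification, reflex-based amplitude
    normalization, moving-RMS tonic amplitude analyses (ongoing and
    time-locked), and fully within-subject 2x2x2 repeated-measures ANOVA with
    paired t contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
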