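Package: tcdfourier
Title: Eighth-Order Fourier Modelling of Transcranial Doppler Blood Flow
    Velocity Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models transcranial Doppler (TCD) cerebral blood flow velocity
    (CBFV) envelope waveforms with truncated eighth-order Fourier series.
    Provides the standardized waveform model V0(t) (cardiac cycle 0.8 s,
    velocity range 50-80 cm/s), its patient-specific affine rescaling Vx(t)
    indexed by systolic peak, end-diastolic trough and heart rate, beat
    segmentation with dicrotic-notch rejection, cycle standardization,
    least-squares harmonic fitting with coefficient averaging, validation
    statistics (deviation integral, one-sample Kolmogorov-Smirnov screen,
    t-based 95 percent confidence intervals against a 3 cm/s agreement
    threshold), and a synthetic TCD cohort generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
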