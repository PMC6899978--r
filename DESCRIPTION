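Package: girfpulse
Title: Time-Optimal Simultaneous Multi-Slice Refocusing Pulse Design Under
    Gradient Imperfections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint optimal-control design of minimum-duration radio-frequency
    (RF) pulses and slice-selective gradient waveforms for simultaneous
    multi-slice (SMS) spin-echo refocusing, with the gradient system's
    measured or synthetic impulse response function (GIRF) inside the design
    loop.  Provides a spin-domain (Cayley-Klein) Bloch simulator, FFT-based
    linear time-invariant gradient filtering with its adjoint, a PINS/SLR
    initializer that satisfies all hardware constraints, Lp-penalized slice
    profile and phase constraints with adaptive weights and exponent
    continuation, exact adjoint first derivatives, a projected limited-memory
    quasi-Newton lower-level solver, and a bilevel minimum-duration search.
    Designed gradient waveforms are pre-emphasized so that the realized
    (GIRF-filtered) gradient produces the prescribed refocusing profile while
    the demanded waveform respects peak amplitude and slew-rate limits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
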