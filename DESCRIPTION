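Package: baroloop
Title: Closed-Loop Lumped-Parameter Hemodynamics with Baroreflex Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the systemic circulation as a closed-loop 0D
    (lumped-parameter) circuit: a time-varying elastance left ventricle with a
    nonlinear internal resistance, diode heart valves, a compartmental
    surrogate of the large arteries with wall properties derived from an
    empirical pulse-wave-velocity relation, per-outlet three-element
    Windkessel boundaries, and an arteriole/venule/vein chain closing at a
    passive left atrium. An arterial baroreflex feedback model (afferent
    carotid pressure index, sympathetic/parasympathetic sigmoids, five
    first-order control ODEs) regulates heart period, maximum elastance,
    peripheral resistance, venous compliance and venous unstressed volume.
    Includes a virtual head-up tilt protocol driven by a rotating gravity
    vector, a Windkessel tuning loop targeting mean and pulse aortic
    pressure, per-beat hemodynamic metrics, and analytic test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
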