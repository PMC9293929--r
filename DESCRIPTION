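Package: glucoloop
Title: Closed-Loop Blood Glucose Regulation Simulator for Type-1 Diabetes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates closed-loop regulation of blood glucose for type-1
    diabetic patients under unannounced meals. The plant is the Bergman
    minimal model (plasma glucose, remote insulin action, plasma insulin)
    driven by decaying-exponential meal disturbances; the controller is a
    three-step backstepping law, optionally augmented with a Lyapunov-based
    adaptive estimator of the meal disturbance. Includes actuator-fault and
    controller-dropout stress scenarios, clinical glycemic zone metrics
    (hypoglycemia / safe / warning / hyperglycemia), scenario configuration
    via YAML, CSV/JSON result serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
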