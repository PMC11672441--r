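Package: prediag
Title: Fuzzy Inference Engines for Canine Disease Pre-Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pre-diagnosis toolkit that ranks candidate dog diseases from
    owner-observed symptoms using fuzzy inference over a relational
    symptom-disease knowledge base. Implements a multi-layered neuro-fuzzy
    learner (MNFL) that penalizes body-part-inconsistent inputs, a hybrid
    fuzzy association learner (FHAL), and a possibilistic fuzzy c-means
    baseline with regularization (PFCM-R), together with a seeded synthetic
    knowledge-base generator and a noise-robustness benchmark reporting
    top-1 and top-3 retrieval accuracy under progressively corrupted queries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
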