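Package: disinfectr
Title: Kernel-Regression Modeling and Genetic-Algorithm Optimization of
    Seed Disinfection Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models microbial contamination of in vitro cannabis seed
    cultures as a function of disinfectant concentrations (sodium
    hypochlorite, hydrogen peroxide) and immersion time using a
    generalized regression neural network (Gaussian-kernel
    Nadaraya-Watson regression with a single spread parameter), and
    searches protocol space for the disinfection regime minimizing
    predicted contamination with a real-coded genetic algorithm
    (roulette-wheel selection, two-point crossover, uniform mutation).
    Includes exact reconstruction of replicate-level observations from
    published mean and standard-error summaries of discretized
    contamination percentages, train/test evaluation metrics (R-squared,
    RMSE, mean bias error), a binomial dose-response simulator for
    end-to-end validation against a known contamination surface, and a
    seeded, reproducible analysis pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
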