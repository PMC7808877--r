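Package: ernfactor
Title: Hierarchical Factor Models for Error-Related Negativity Amplitudes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychometric analysis of the error-related negativity (ERN)
    elicited by multiple Flanker-task variants. Provides a synthetic-data
    generator with a known second-order latent structure (a General ERN over
    task-specific factors, plus correlated personality trait domains),
    response-locked epoch scoring with channel-level artifact rejection,
    trial-level outlier screening and unit binning, a confirmatory
    factor-analysis engine with full-information maximum likelihood for
    missing cells and the usual fit indices (CFI, TLI, RMSEA, SRMR, AIC,
    BIC), an iterative indicator-pruning model search, regression-method
    latent score estimation, and multitrait-multimethod validity and
    profile-similarity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
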