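Package: driftal
Title: Active Learning on Dynamic Clustering for Electronic-Nose Drift Compensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pool-based active learning for online drift compensation of
    electronic-nose (gas-sensor-array) classifiers. Implements a kernel
    extreme learning machine learner, the classical uncertainty-sampling,
    query-by-committee and expected-error-reduction selectors, the adaptive
    confidence rule, and a dynamic-clustering selector that balances the
    class composition of queried labels by clustering the unlabeled pool
    with class-mean-seeded k-means iterations and selecting instances
    cluster-by-cluster under a flag-vector alternation scheme. Includes
    long-term and short-term batch-wise drift evaluation protocols, the
    label efficiency index, a reader for the sparse text format of the
    public gas-sensor drift benchmark, transient-response feature
    extraction (steady-state and exponential-moving-average features), and
    a synthetic drifting-batch generator so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
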