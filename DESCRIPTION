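Package: soschoa
Title: Chimp Optimization with Social Coevolution and Sine Chaotic
    Opposition Learning for Feature Selection
Version: 0.1.0
Authors@R:
    person("Li", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Binary wrapper feature selection for high-dimensional
    biomedical classification data (few samples, hundreds to thousands
    of features) driven by the Chimp Optimization Algorithm (CHoA) and
    its SOSCHoA variant, which augments CHoA with a social-coevolution
    position update and dimension-wise sine-chaotic opposition learning
    under greedy replacement. Candidate feature subsets are scored by a
    k-nearest-neighbour wrapper fitness combining classification error
    and subset size. Includes a seeded generator of microarray-like
    labeled datasets with planted informative, redundant and noise
    features, the repeated-run evaluation protocol (accuracy, subset
    size and fitness summaries, convergence and population-diversity
    curves, Wilcoxon rank-sum comparisons), CSV and MAT-file dataset
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
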