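Package: growthwarp
Title: Clustering Bacterial Growth Curves by Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Shape-based clustering of bacterial growth curves (OD600 time
    series) of unequal length. Pairwise similarity is measured with dynamic
    time warping (DTW) and derivative DTW (DDTW), combined through a weight
    alpha in [0, 1], and the resulting distance matrix is clustered with
    Ward's agglomerative linkage. Cluster quality is scored with the
    silhouette coefficient, adjusted Rand index, adjusted mutual information
    and V-measure, and the weight and cluster count are selected on an
    alpha-by-N grid by a majority-vote error benchmark with knee-based model
    selection. Includes a Gompertz-based simulator of media-differentiated
    growth curves for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
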