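# Metric and feature identifiers shared across modules.

COHORT_METRICS <- c("mutual_information", "canonical_correlation", "pearson",
                    "spearman", "pca_variance", "coefficient_of_variation",
                    "js_divergence")

DISTANCE_METRICS <- c("manhattan", "euclidean", "chebyshev", "cosine",
                      "mahalanobis")

FEATURE_IDS <- c("regulation_score", "gene1", "gene2", "product", "ratio",
                 "expression", DISTANCE_METRICS)
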