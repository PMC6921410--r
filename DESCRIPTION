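Package: starclus
Title: Ranking-Based Clustering of Star-Schema Heterogeneous Information
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Clusters the target objects of a star-schema heterogeneous
    information network (for example, traditional Chinese medicine formulas
    linked to herbs, functions and symptoms) while simultaneously ranking
    objects of every type within each cluster.  Authority-style rankings are
    computed by power iteration on bipartite relation matrices, turned into a
    per-cluster generative model by Jelinek-Mercer smoothing against the
    global ranking, and combined with EM-estimated cluster priors to give
    posterior cluster memberships.  Targets are embedded in the concatenated
    posterior space and assigned to clusters by cosine distance until the
    partition stabilises.  Includes a planted-partition synthetic network
    generator, the fraction-of-vertices-identified-correctly (FVIC) accuracy
    metric, semi-supervised seeding through a Dirichlet prior, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
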