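Package: canx
Title: Cascading Collective Anxiety Estimation for Topic-Based Online Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the collective anxiety of topic-based online communities
    from member profiles, message text, and the community relation graph.
    Individual anxiety scores combine a profile-based scorer calibrated against
    Zung Self-Rating Anxiety Scale (SAS) records with a lexicon/embedding-based
    topical factor; scores are then propagated over the symmetric member
    relation matrix by an exponential-propagation cascade and aggregated to a
    normalized community-level score and its daily time series.  Companion
    tools score per-message declarative knowledge (source credibility, topic
    similarity, and a word-list readability index), assess affective
    polarization (trend and fluctuation of the daily series), validate ordinal
    anxiety ratings with directional precision/recall, and run the hypothesis
    battery linking topic traits, knowledge, and influencer ratio to collective
    anxiety.  A seeded synthetic-community generator with known ground truth
    makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
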