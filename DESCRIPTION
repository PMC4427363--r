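Package: opinionkb
Title: Indirect Opinion Mining of Drug Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mines indirect opinions -- opinions on a drug expressed through its
    effect on another entity -- from structured patient drug reviews. Builds a
    polarity-tagged corpus and a deduplicated knowledge base of
    (effective entity, affected entity, effect, polarity) quadruples from
    reviews with separate benefits and side-effects fields, scores affected
    semantic groups by SGF-IOF weighting, resolves missing effective entities
    through a counted relation-triple store and a four-stage filter cascade,
    assigns polarity via domain knowledge, valence shifters, conjunction rules
    and review structure, and classifies new sentences by knowledge-base lookup
    with semantic-type and semantic-group pattern backoff. Includes a
    seed-deterministic synthetic review generator with planted ground truth and
    an evaluation harness reporting precision, recall and F-measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
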