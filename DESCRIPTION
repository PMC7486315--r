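Package: arenosae
Title: Structured Taxonomic Descriptions, Identification Keys and
    Species-Delimitation Summaries for Silene sect. Arenosae
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ontology-driven structured descriptive data for plant taxonomy:
    controlled vocabularies and pro-forma description templates, descriptive
    elements with quantitative ranges, qualitative states, relative scores and
    modifiers, constant-feature intersection and parent/child factoring,
    telegraphic natural-language rendering with parenthetical-extreme range
    notation, and a three-valued dichotomous key engine.  Also recomputes
    posterior cluster similarity matrices from multispecies-coalescent
    species-tree samples (burn-in, collapse-height partitioning, co-clustering
    frequencies, summary-topology sorting).  Ships the descriptions and the
    identification key of Silene sect. Arenosae (Caryophyllaceae) as packaged
    fixtures, plus generators for synthetic descriptions and tree posteriors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
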