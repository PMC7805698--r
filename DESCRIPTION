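Package: latchmem
Title: Latching Attractor Memory with Working Memory, Object-Place Binding
    and Episodic Replay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation library for a three-network cognitive memory model:
    a content-addressable identification (WHAT) network implemented as a
    fully connected attractor network with Hebbian storage, gain- and
    noise-modulated dynamics and short-term synaptic depression; a
    winner-take-all localization (WHERE) network over orthogonal place
    codes; and a prefrontal-style working memory that recruits nodes for
    novel object-place conjunctions and biases recall toward recent
    experience. Delayed predictive associations between attractor states
    support episodic sequence replay, and a comparator produces total and
    feature-specific surprise signals. Ships seeded task runners for
    pattern completion, place and object recall, the A-not-B task, delayed
    matching to sample, semantic mind-wandering, episodic recall with
    sequence blending, and vicarious trial and error, together with
    trace-analysis utilities (energy traces, principal-component
    projections, attractor event logs, transition matrices).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
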