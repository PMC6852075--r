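Package: symcoop
Title: Transmission, Relatedness and the Evolution of Cooperative Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical and simulation models of symbiont cooperation under
    mixed vertical and horizontal transmission. Provides closed-form and
    numeric solvers for the evolutionarily stable level of symbiont
    cooperation from an inclusive-fitness (neighbour-modulated fitness)
    analysis, a demographic closure expressing whole-group relatedness in
    terms of transmission mode and infection bottleneck sizes, marginal-effect
    and route decompositions separating the direct influence of transmission
    mode from its influence via relatedness, an individual-based
    Wright-Fisher-style simulator of the host-symbiont life cycle that
    exhibits evolutionary branching, summary statistics over simulated
    populations (realized whole-group relatedness, trait-mode detection,
    branching classification), and parameter-sweep reporting.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
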