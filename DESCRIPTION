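Package: ancdnet
Title: Optimisation of Centralised Anaerobic Co-Digestion Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning the feed of a network of anaerobic
    digestion plants that accept organic waste from multiple external
    generators.  Substrate volumes are discretised into fixed quanta and
    allocated over the bipartite generator-receptor graph so as to
    maximise a normalised quality-plus-logistics cost index, subject to
    biochemical feasibility of every receptor's blend (intake capacity,
    COD/TN ratio, alkalinity, lead toxicity).  Three interchangeable
    stochastic solvers are provided (a max-min ant colony system, a
    genetic algorithm with elitism, and particle swarm optimisation),
    together with an exhaustive oracle for small instances, a scenario
    engine, benchmark and parameter-sweep harnesses, truck logistics
    schedules, a synthetic network generator and a command-line
    interface.  A characterised case-study network of 19 waste
    generators and 3 receptor plants is bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
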