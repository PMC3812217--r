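Package: fluxdom
Title: Elementary Flux Mode Analysis of Metabolic and Functional-Domain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact enumeration of elementary flux modes (EFMs) for small and
    medium metabolic networks, with first-class support for networks in which
    enzymes are decomposed into their functional protein domains (catalytic
    sites and ligand-binding domains, the latter modelled as species that form
    enzyme-bound complexes). All flux algebra is carried out in exact integer
    arithmetic: modes are returned as coprime integer vectors and support
    minimality is decided by exact rank tests, never by floating point
    tolerances. Includes a double-description enumerator in the metatool
    lineage, an independent brute-force oracle for small networks, reaction
    and domain knockout (inhibition) analysis of the mode set, readers and
    writers for the metatool plain-text network format, an SBML importer, a
    seeded random-network generator for property testing, and curated
    Bacillus subtilis fixtures: the pyruvate dehydrogenase complex as a
    functional-domain network and the TCA cycle in both classical and
    domain-resolved form.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
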