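---
title: "Elementary flux modes of functional-domain metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elementary flux modes of functional-domain metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxdom)
```

## The model

A metabolic network is a set of reactions over metabolites, each metabolite
flagged *internal* (mass-balanced at steady state) or *external* (free
source/sink). Writing $S$ for the stoichiometric matrix restricted to
internal metabolites, the steady-state flux cone is

$$ C = \{\, v \in \mathbb{R}^n : S v = 0,\; v_r \ge 0
         \text{ for every irreversible reaction } r \,\}. $$

An **elementary flux mode** (EFM) is a vector $v \in C$, $v \neq 0$, whose
support (the set of reactions with non-zero flux, signed by direction for
reversible reactions) contains no other cone vector's support as a proper
subset. Equivalently — and this is the test `is_elementary()` applies — the
nullspace of $S$ restricted to the support columns is one-dimensional. EFMs
are the minimal steady-state pathways of the network: every steady-state
flux distribution is a non-negative combination of them, and knocking out a
reaction removes exactly the modes whose support contains it.

### Functional-domain networks

Most enzymes are multi-domain proteins, and each domain carries an
elementary activity: catalysis, ligand binding, or regulation. A
*functional-domain network* replaces each enzyme-level reaction with the
elementary steps its domains perform. The package represents the three
roles differently, following how such networks are drawn:

* **catalytic** domains annotate a step (`catalysts` on a `reaction`);
  they have no stoichiometric effect;
* **binding** domains are *species*: the free domain and its ligand
  complexes (e.g. `Mdh1`, `Mdh1_NAD`, `Mdh1_NADH`) enter the stoichiometry
  of binding, catalytic and release steps, and cycle as conserved moieties;
* **regulatory** domains are vocabulary only.

This is why domain inhibition is more informative than enzyme deletion:
`reactions_of_domain()` finds every step a domain touches — through
annotation or through its complex species — and `inhibit()` removes the
modes supported on those steps. In the bundled TCA network the NAD/FAD
binding domain of lipoamide dehydrogenase (PdhD2, SCOP fold c.4.1) is
shared by the pyruvate dehydrogenase and 2-oxoglutarate dehydrogenase
complexes, so blocking its three steps (R5–R7) removes five of the six
modes, among them both ATP producers — an effect invisible at enzyme
resolution, where the corresponding knockout leaves an ATP-producing mode
alive.

## Enumeration algorithm and exactness

`enumerate_efms()` is a double-description enumerator in the metatool
lineage. Every reversible reaction is split into a forward and a backward
column, so the cone becomes $\{v \ge 0, S'v = 0\}$; the hyperplanes
$S'_i v = 0$ are processed one at a time starting from the unit rays of the
orthant, combining positive/negative ray pairs and keeping a combination
only if the pair is adjacent (no third ray's support lies inside the union
of the pair's supports — the classical combinatorial test, exact for
pointed cones). Extreme rays of the split cone are exactly the EFMs of the
split network; after recombining forward and backward halves, the futile
two-cycles of split pairs are discarded and reversible-only modes are kept
in one orientation.

All arithmetic is exact. Coefficients are held as integers (rational input
is cleared row-wise, which leaves the nullspace unchanged); every ray is
reduced to coprime integers after each combination; rank and determinant
use fraction-free Bareiss elimination. There are **no tolerance
parameters** anywhere: support minimality under floating point is the
dominant correctness risk of EFM codes, and it is removed by construction.
A guard aborts (rather than silently overflowing) if any intermediate
integer exceeds $2^{49}$; the sparse biochemical matrices handled here stay
far below it.

Canonical form: coprime integers; modes supported entirely on reversible
reactions are oriented so their first support entry (network declaration
order) is positive. Output order is (support size, lexicographic signed
support) — published mode numberings are arbitrary, so the fixtures map
paper labels to supports by content, not by position.

`brute_force_efms()` is the independent oracle: it enumerates reaction
subsets directly, keeps those whose restricted matrix has a
one-dimensional exact kernel with full-support, sign-feasible generator
(kernel via Cramer expansion over a maximal independent row set), and
shares nothing with the double-description path beyond the integer
primitives. It refuses networks above 15 reactions; the suite runs both
paths on 200 seeded random networks of up to 8 reactions and on the
13-reaction classical TCA fixture and requires set equality of canonical
signed supports.

Degenerate inputs behave predictably: an empty network has no modes; a
network with no internal metabolites yields one mode per irreversible
reaction direction; an isolated internal reversible pair supports no
steady-state flux (the forward+backward two-cycle is not a mode).

## The bundled B. subtilis networks

Three fixtures ship with the package, each carrying the expected canonical
signed supports of its modes and self-testing against them
(`fixture(name, self_test = TRUE)`):

* `pdh_domain` — the pyruvate dehydrogenase complex as seven elementary
  steps (decarboxylation on PdhA, reductive acetylation on PdhB1,
  transacetylation on PdhC3, dihydrolipoamide reoxidation on PdhD3, and
  NAD binding / electron transfer / NADH release on the PdhD domains).
  One mode, containing every step, with overall reaction
  Pyr + NAD + CoA → AcCoA + CO~2~ + NADH.
* `tca_classical` — the enzyme-level TCA cycle, 13 reactions, six modes.
* `tca_domain` — the domain-resolved TCA cycle, steps R1–R33, six modes
  in overall-reaction bijection with the classical six.

The exact stoichiometries of the published models are not printed in the
source tables, so the fixtures are reconstructed from standard
*B. subtilis* TCA biochemistry under the hard constraint that the
enumerated modes equal the published listings verbatim. The choices this
forces, all documented in the bundle notes:

* succinyl-CoA synthetase is authored in the succinyl-CoA-*forming*
  direction (`SucCD: Suc + CoA + ATP = SucCoA + ADP`), so the oxidative
  cycle runs it backwards (`-SucCD`) and that is where the cycle's ATP is
  made;
* the glycolysis input is a lumped pyruvate source without ATP
  bookkeeping and the acetyl-phosphate node is a lumped reversible
  AcCoA ⇌ AcP shuttle; with these conventions exactly two modes per
  representation are net ATP producers;
* NAD(P) is not distinguished and phosphate/water are not tracked —
  identically on both representations, so classical and domain modes
  match by overall reaction without aliases;
* PDH and ODH keep separate lipoyl pools (`LA_E`/`DHA_E` vs
  `LA_Eo`/`DHA_Eo`). If they shared one pool, the two reoxidation steps
  R4 and R14 would be stoichiometrically identical and the published
  PDH+ODH mode (both at coefficient 1) could not be elementary. The ODH
  thiamine intermediate is named `HSuc-TPP`, a synthetic label absent
  from the published abbreviation table;
* the published mode signs force two different authoring directions for
  NADH-handling steps: R29 is NADH *release* from Mdh1 (so forward malate
  dehydrogenase flux prints `R28 R29`), while R31 is NADH *binding* to
  ywkA2 (so forward malic-enzyme flux prints `R30 -R31`). Both are
  followed verbatim;
* the CoA-binding domain SucD1 is an external node, as in the published
  network, and citZ is annotated but carries no step.

The doubled flux through the shared lipoamide dehydrogenase steps — the
PDH+ODH modes carry coefficient 2 on R5, R6, R7 while each complex runs
once — emerges from the enumeration; it is not encoded anywhere.

## Inhibition and comparison semantics

`inhibit(net, efms, target)` partitions the mode set by support
intersection with the target reactions (a domain label is first resolved
via `reactions_of_domain()`); *lost capabilities* are the external
metabolites some removed mode produced that no surviving mode can. The
suite checks that this filtering semantics coincides with re-enumerating
the reaction-deleted network for every reaction of every fixture and on
random networks — the two standard knockout readings agree exactly.

`compare_representations()` matches modes across representations by equal
overall-reaction maps, after passing external metabolite ids through an
optional alias table (needed when the two representations name their
exchanged species differently; the bundled fixtures share one vocabulary,
so no aliases are required). Matching is by content and reported
symmetrically; unmatched modes are listed, never raised as errors.

## The random-network generator

`random_network()` emulates the small, sparse, mostly unimolecular
networks on which exhaustive oracle verification is feasible: one external
source, one sink, every internal metabolite placed in at least one
reaction, coefficients in {1, 2}, reversibility by coin flip, weak
connectivity enforced by retry under a fixed seed. It does not emulate
real metabolism's hubs, cofactor coupling or multi-substrate reactions —
those features are exercised by the curated fixtures instead. Passing the
oracle sweep therefore demonstrates algorithmic correctness on the cone
geometry, not biological realism; the fixture self-tests carry the
biological content. Test problem sizes — 200 networks of 3–8 reactions,
plus the 7-, 13- and 33-reaction fixtures — keep the whole suite around a
quarter of a minute while covering every combination path the enumerator
has (the 33-step domain network enumerates in well under a second).

## Limitations

* The enumerator is for small and medium networks; no network
  compression, parallelism or genome-scale performance engineering is
  attempted, and the brute-force oracle is capped at 15 reactions.
* Enzyme-to-domain decomposition is curated input
  (`domain_network_spec()`), not computed: structural modelling and
  SCOP/PFAM assignment are outside the package's scope.
* SBML support is import-only (core level 2/3 constructs; rules, events
  and constraints are rejected explicitly); kinetics, concentrations,
  thermodynamics and flux optimization are out of scope throughout.
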