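---
title: "From annotated gene clusters to flux: the bgcflux model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From annotated gene clusters to flux: the bgcflux model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcflux)
```

## The model

`bgcflux` treats an NRPS/PKS biosynthetic gene cluster as a collinear
assembly line. The reconstruction rests on three assumptions:

1. **Collinearity** — modules act in gene genomic order, and within a gene
   in translation order. Clusters that violate this (for example two
   parallel initiating genes encoding product variants) are reconstructed
   as one linear pathway; this is documented behaviour, not corrected.
2. **One elongation per module** — iterative modules are not modelled; an
   active extending module contributes exactly one condensation.
3. **Lumped chain chemistry** — the growing chain is a pseudo-metabolite
   (`chain_0`, `chain_1`, …) without an elemental formula. Mass balance is
   therefore asserted only where it is meaningful: cofactors (ATP, NADPH,
   SAM/SAH), small molecules (CO₂, H₂O, phosphates) and the carrier-protein
   pool, all of which the test suite audits by summing stoichiometries.

Each domain kind maps to a fixed reaction template (see the README table).
Beyond the templates, activity resolution decides which modules fire:

* a module after the first thioesterase/thioester-reductase contributes
  nothing (chain release is terminal);
* a KR annotated inactive silences the module's DH and ER, because both act
  on the hydroxyl moiety the KR produces; a KR with *unknown* activity
  defaults to **active** — inactive calls by annotation tools are a known
  error source while genuinely inactive KRs are rare, so the active default
  minimises expected domain-level error;
* an oMT inside a PKS module marks the module non-extending (a recognised
  KS-deactivation signature);
* a cross-gene KS | DH,ACP arrangement in a trans-AT cluster is a
  dehydratase-docking (DHD) module and is inactive;
* module chemistry decides `module_kind` in hybrids: a KS makes it PKS, a
  C/Cy makes it NRPS, a tie goes to PKS so that the extension reaction is
  unique.

Every one of these decisions is written to a per-module log
(`plan$decisions`, exportable as TSV), so a reconstruction is auditable
rule by rule.

## Chain initiation

Six load descriptors cover the initiation chemistries: the standard PKS
(AT+ACP) and NRPS (A+carrier) loads, CAL (generic or recognised starter +
carrier, releasing water), GNAT (decarboxylating acetyl transfer from
malonyl-CoA), FkbH (1,3-bisphosphoglycerate dephosphorylation, two
phosphates released) and the C-acylated NRPS start, where a condensation
domain in the initiating module acylates the first amino acid. The acyl
donor there is a *generic fatty acid* pool sourced from the reference
model's fatty-acid species, because the true donor specificity is not
annotated. A cluster whose first module is already an extender initialises
the chain from that module's bare monomer, with a warning.

A plan with no terminator anywhere releases by thioesterase-style
hydrolysis and warns. The alternative — a dead-end chain — would make every
downstream flux query trivially zero, which would defeat the purpose of
inserting the pathway at all.

## Extender units and fallbacks

A/AT substrate codes map to reference-model metabolites: the 20
proteinogenic amino acids, malonyl-, methylmalonyl- and ethylmalonyl-CoA,
methoxymalonyl-ACP, and six rare monomers (4-hydroxyphenylglycine,
β-hydroxytyrosine, 2-aminobutyrate, pipecolate, dihydroxyphenylglycine,
3-amino-5-hydroxybenzoate) whose biosynthesis is appended as one lumped
reaction each from common precursors (tyrosine, threonine, lysine, glucose,
1,3-bisphosphoglycerate). Those lumped stoichiometries hide multi-step
routes and are this package's own definitions; only the identity of the
monomer set is externally fixed. Methoxymalonyl-ACP is accepted only when
the cluster carries a gene with its biosynthesis smCOG signature (code
1028 here — again an implementer-defined gate, as is the mapping of
tailoring smCOGs 1256/1062/1002 to NDP-hexose glycosylation and 1084/1109
to C5N-unit attachment; the donors are configurable model species).

Anything unrecognised falls back conservatively: generic amino acid for
NRPS (with 20 irreversible sourcing pseudo-reactions so the pathway stays
functional), malonyl-CoA for PKS. Tailoring reactions are applied in gene
genomic order — their true order is not predictable from annotation, and a
fixed, reproducible order is preferable to a guess.

## The flux layer

All biosynthetic and pseudo-reactions are irreversible with bounds
(0, 1000) mmol gDW⁻¹ h⁻¹. Insertion into a reference model is a pure
function: metabolites resolve by exact id, then by a curated synonym
table, else they are created (cytosolic by default); the final product gets
an irreversible demand reaction which serves as the production objective —
a boundary-reaction objective is portable across solvers. Wild-type growth
is provably unchanged by insertion (the pathway can carry zero flux), and
the suite checks this at 10⁻⁹ relative tolerance.

The analysis procedures use these defaults, each exposed as a parameter:

| parameter | default | meaning |
|---|---|---|
| glucose uptake | 0.8 mmol gDW⁻¹ h⁻¹ | sole carbon source |
| unconstrained uptakes | NH₄⁺, SO₄²⁻, Pi, O₂, H₂O, H⁺ | ions and balancing species |
| `growth_fraction` | 0.9 | growth floor for production scoring |
| `growth_floor` | 0.5 | mutant non-essentiality threshold |
| `ko_growth_fraction` | 0.999 | growth fixation inside the knockout scan |
| `min_gain` | 0.001 | minimal relative production gain reported |

The production-versus-scan growth fractions (0.9 vs 0.999) are deliberately
separate parameters with separate defaults. A reaction knockout is both
bounds set to zero; "non-essential" is operationalised as mutant growth at
or above `growth_floor` of wild type, collapsing essentiality and the
growth-reduction limit into one criterion rather than inventing a second
threshold. Infeasible mutant LPs are treated as essential and logged.

### The LP solver

No linear-programming library exists in this R stack, so the package
carries a dense two-phase primal simplex (~90 lines) with Bland's
anti-cycling rule. Problems are normalised to standard form: variables
shifted by their lower bounds, fixed variables eliminated into the
right-hand side, slack variables for upper bounds, rows negated to keep the
right-hand side non-negative. Pivot tolerance is 10⁻⁹; infinite bounds
clamp to ±1000. Only objective *values* are contracted to be reproducible —
flux vectors may differ between alternate optima. The solver is validated
three ways: hand-derived rational optima of the toy network, a second
independently assembled formulation, and cobrapy/GLPK reading the same SBML
files in the test suite.

## What the toy model emulates — and what it does not

`build_toy_reference_model()` is a ~40-reaction stand-in for a bacterial
host GEM, with every coefficient a small rational so optima are exact:
lumped glycolysis (2 ATP/glucose), capacity-limited respiration (10
ATP/acetyl-CoA, upper bound 0.3 by default), an NADPH-producing
pentose-phosphate lump, six amino acids, malonyl/methylmalonyl-CoA, a
SAM/SAH cycle, fatty-acid and NDP-hexose pools, and a biomass reaction.
The deliberate design element is the gene-annotated acetate-overflow
fermentation `FER`: it raises maximal growth at a carbon cost, so deleting
it lowers the growth optimum and frees carbon at the 99.9 %-growth
operating point — the one true knockout candidate, with relative gain
exactly 25/118. Every other gene-annotated reaction is either essential,
drops growth below the 50 % floor, or leaves production unchanged; the
uniqueness argument is enumerated case by case in the test suite.

With the default respiration cap the network is *not* homogeneous (growth
does not scale linearly in the glucose bound); `resp_cap = Inf` restores
homogeneity, and the linear-scaling property is tested on that variant.

Passing tests on this model demonstrate correctness of the calculus,
bookkeeping and LP machinery. They do not demonstrate accuracy on real
clusters: real antiSMASH output has noisier qualifiers, genuinely iterative
modules, KS domains inactivated at the sequence level, and tailoring
enzymes beyond the implemented smCOG families. Domain-level accuracy
against curated pathways requires external data and is outside the offline
test surface.

## Problem sizes and numerical choices

The test and acceptance workloads use 50-cluster randomized populations,
the two-module NRPS flux fixture, and the ~40-reaction toy model with
~25-candidate knockout scans — sizes chosen so the whole suite solves a few
hundred LPs in well under a minute while still exercising every rule at
least once. Degenerate inputs are handled explicitly: clusters with no
assemblable module raise a typed condition; empty GenBank feature tables
and missing FBC bounds are named errors; unknown domains are retained as
`UNKNOWN` and never silently dropped; duplicate rare-monomer subpathways
are deduplicated; ties in module chemistry go to PKS; in-module tailoring
applies methyltransferases first, then KR → DH → ER in catalytic order.

## Known limitations

* Iterative modules, RiPPs, terpenes and type 2/3 PKSs are out of scope.
* The anabaenopeptin-style parallel-initiation architecture is linearised.
* Lumped rare-precursor and tailoring stoichiometries are package-defined.
* No gap-filling, biomass rescaling or compartment inference on insertion.
* The simplex is dense and suited to models up to a few hundred reactions;
  genome-scale hosts with thousands of reactions would need a sparse
  solver backend behind the same `fba()` surface.
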