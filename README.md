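# bgcflux

Automatic translation of annotated biosynthetic gene clusters (BGCs) into
stoichiometric metabolic pathways, and constraint-based analysis of their
production potential in a host genome-scale model.

## The problem

Non-ribosomal peptide synthetases (NRPS) and type 1 / trans-AT polyketide
synthases (PKS) are assembly lines: ordered modules of functional domains
that each load one monomer (an amino acid or a malonyl-CoA-family thioester),
condense it onto the growing chain, optionally tailor the new unit
(ketoreduction, dehydration, enoylreduction, methylation), and finally
release the product. Genome-mining tools such as antiSMASH annotate these
domains and modules from sequence, but turning that annotation into an
explicit reaction list — with substrates, redox cofactors and energy
demand — is what makes a BGC usable inside a genome-scale metabolic model
(GEM), and doing it by hand is slow and error-prone.

`bgcflux` automates the translation. For every active module it emits the
domain-calculus reactions

| domain | reaction |
|---|---|
| A | ATP + AA + PCP → AA-PCP + AMP + PPi |
| AT | acyl-CoA + ACP → acyl-ACP + CoA |
| C / Cy | AA-PCP + Xₙ → Xₙ₊₁ + H₂O + carrier |
| KS | acyl-ACP + Xₙ → Xₙ₊₁ + CO₂ + carrier |
| KR / ER | NADPH + H⁺ + Xₙ → Xₙ + NADP⁺ |
| DH | Xₙ → Xₙ + H₂O |
| cMT / nMT / oMT | SAM + Xₙ → Xₙ + SAH |
| TE | H₂O + Xₙ → product |
| TD | NADPH + H⁺ + Xₙ → product + NADP⁺ |
| CAL / GNAT / FkbH | alternative chain-initiation chemistries |

(Xₙ is the lumped chain intermediate after n elongations.) On top of the
calculus sit the heuristics that real clusters need: bridging modules
assembled across gene boundaries, dehydratase-docking (DHD) modules marked
inactive, oMT-containing PKS modules treated as non-extending, the
KR-activity cascade that silences DH/ER, C-acylated NRPS starts, rare
extender units with lumped biosynthesis subpathways, generic amino-acid
fallbacks, and smCOG-driven post-release tailoring.

The reconstructed pathway is inserted into a reference GEM and analysed
with flux balance analysis (FBA):

* **production rate** — maximize the product demand with growth constrained
  to at least 90 % of its maximum;
* **knockout scan** — brute-force single-reaction deletions over all
  gene-annotated, non-essential reactions (mutant growth ≥ 50 % of wild
  type), scoring production at 99.9 % of the mutant's maximal growth and
  reporting every knockout that beats wild type by more than 0.1 %.

## Worked example

```r
library(bgcflux)

spec <- bgc_spec("nrps1", classes = "NRPS",
  genes = list(gene_spec(modules = list(
    module_spec(c("A", "PCP"), specificity = c(A = "ala")),
    module_spec(c("C", "A", "PCP", "TE"), specificity = c(A = "gly"))))))

cluster <- parse_region(write_synthetic_region(spec))
plan    <- assemble_modules(cluster)
model   <- build_toy_reference_model()
pathway <- build_pathway(plan, model)
tidy(pathway)
#> # A tibble: 4 × 7
#>   rxn_id       name                            lb    ub genes     provenance
#> 1 nrps1_M01_A  load module adenylation          0  1000 <chr [1]> A
#> 2 nrps1_M02_A  module 2 adenylation loading     0  1000 <chr [1]> A
#> 3 nrps1_M02_C  module 2 condensation (C)        0  1000 <chr [1]> C
#> 4 nrps1_M02_TE chain release (TE)               0  1000 <chr [1]> TE
#>   equation
#> 1 atp_c + ala__L_c + nrps1_carrier_c --> nrps1_chain_0_c + amp_c + ppi_c
#> 2 atp_c + gly_c + nrps1_carrier_c --> nrps1_M02_loaded_c + amp_c + ppi_c
#> 3 nrps1_M02_loaded_c + nrps1_chain_0_c --> nrps1_chain_1_c + h2o_c + ...
#> 4 h2o_c + nrps1_chain_1_c --> nrps1_product_0_c + nrps1_carrier_c

extended <- insert_pathway(model, pathway)
max_production(extended)
#>   product                  wt_max_growth growth_fraction_used production_rate
#> 1 DM_nrps1_product_0_c              0.15                  0.9          0.0681

tidy(knockout_scan(extended))
#> # A tibble: 1 × 4
#>   rxn_id mutant_max_growth mutant_production relative_increase
#> 1 FER                 0.11          0.000825             0.212
```

Reading the numbers: the host grows at 0.15 h⁻¹ on 0.8 mmol gDW⁻¹ h⁻¹
glucose; with growth pinned at 90 % of that, the dipeptide product can be
made at 0.068 mmol gDW⁻¹ h⁻¹. The scan finds exactly one useful knockout —
the acetate-overflow fermentation `FER`, which boosts growth at a carbon
cost; deleting it drops maximal growth to 0.11 h⁻¹ but raises production at
the 99.9 %-growth operating point by 21 % over wild type. All three numbers
are exact rationals of the toy network (3/20, 177/2600, 25/118), which is
what the test suite pins them to.

A command-line interface wraps the same functions
(`exec/bgcflux reconstruct | insert | analyze | knockout-scan | fixtures`),
reading antiSMASH region GenBank files and SBML L3+FBC models and writing
pathway JSON, extended SBML and tab-separated scan tables.

## Scope

Supported cluster classes are NRPS, type 1 PKS and trans-AT PKS (and their
hybrids). RiPPs, terpenes, type 2/3 PKSs, iterative modules,
sequence-level active-site prediction and chemical-structure (SMILES)
output are out of scope. Large-scale replication against public BGC
repositories requires network access and curated references and is not part
of the test surface.
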