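---
title: "Refactoring bacterial genome organization under a linear transcription model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refactoring bacterial genome organization under a linear transcription model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrnr)
```

## The problem

Bacterial genomes scatter functionally related genes across hundreds of
independently regulated operons. Genome refactoring asks whether that
internal organization can be radically simplified — genes regrouped into far
fewer operons, regulation rewired — while the cell's *external* behavior,
its transcriptome-wide response to environmental change, is preserved.
`gtrnr` implements an automated design loop for this question: a genome-scale
transcription model provides the phenotype, a stochastic search rearranges
the genotype, and a compiler turns the winning regulatory network into a
concrete annotated nucleotide sequence.

## The transcription model

Each gene $i$ carries a single mRNA variable $y_i$ obeying the linear ODE

$$\frac{dy_i}{dt} = \alpha_i + \sum_j \beta_{ij}\, y_j +
  \sum_k \gamma_{ik}\, \Delta v_k - \delta_i\, y_i,$$

where $\alpha_i$ is the constitutive transcription rate of the promoter
driving gene $i$'s operon, $\beta_{ij}$ the (signed) regulatory effect of
transcription factor $j$, $\gamma_{ik}$ the effect of environmental factor
$k$ — a metabolic uptake flux, entering as the deviation
$\Delta v_k = v_k - v_k^{\mathrm{opt}}$ from its optimal value (mmol g⁻¹
h⁻¹) — and $\delta_i$ the degradation-plus-dilution rate constant (h⁻¹).
Expression units are arbitrary: the model is inferred and compared on the
same scale, so only relative agreement matters.

The $(\alpha, \beta, \gamma)$ triple belongs to the *promoter*, not the
gene. An operon's genes all share the *effective regulation* of the operon:
the elementwise sum of the primary promoter's triple and the triples of up
to three tandem promoters fused upstream of it. Tandem combination is
strictly additive; promoter interference is deliberately not modelled
(promoter pairs are assumed separable by a suitable isolation spacer).
Translation and post-transcriptional regulation are out of scope.

The steady state solves $(D - B)\,y = \alpha + \Gamma \Delta v$ with
$D = \mathrm{diag}(\delta)$. Numerical choices:

* The system is declared ill-conditioned (hard error naming the most
  implicated genes) when the reciprocal condition number falls below
  $10^{-12}$.
* A linear model can produce negative steady states; components below zero
  are clipped to zero after solving and the affected genes are reported in
  the `clipped` attribute. Fitness and all metrics use the clipped profile.
* Instability (an eigenvalue of $B - D$ with nonnegative real part) is a
  warning, not an error: the algebraic steady state is still defined and
  returned.
* `simulate_dynamics()` integrates the same ODE with a stiff solver
  (`deSolve::lsoda`, rtol $10^{-10}$); it is the independent numerical
  route used to cross-check the algebraic solve in the test suite.
* `response_time()` — how long the transcriptome needs to settle within a
  fraction $\varepsilon$ (default 0.05, max-norm) of the new steady state
  after an environmental switch — is computed from the eigendecomposition
  of $B-D$, with the final crossing refined by root bisection.

## The objective

A candidate genome is scored against the wild type by
$$S = w_{\mathrm{exp}} S_{\mathrm{exp}} + w_{\mathrm{mod}} S_{\mathrm{mod}},$$
both components $\le 0$ with 0 best.

$S_{\mathrm{exp}}$ is the negated mean normalized squared deviation of the
candidate steady-state profile from the wild type over the scored gene set
$G$ and environment set $E$:
$$S_{\mathrm{exp}} = -\frac{1}{|G||E|}\sum_{g,e}
  \frac{(y^{\mathrm{cand}}_{ge} - y^{\mathrm{wt}}_{ge})^2}
       {(y^{\mathrm{wt}}_{ge})^2 + \epsilon},$$
with $\epsilon = 10^{-6}$ guarding genes whose wild-type expression is near
zero. $G$ may be the whole genome or the stress-, defense- or enzyme-tagged
subsets — the four selective pressures under which refactoring is studied.

$S_{\mathrm{mod}}$ rewards genome modularity through the entropy of the
operon-size distribution: with $p_{op} = |op|/N$,
$$S_{\mathrm{mod}} = -\frac{-\sum_{op} p_{op}\ln p_{op}}{\ln(\#\,operons)}
  \in [-1, 0],$$
maximal (0) when all genes share one operon, minimal (−1) for all-singleton
genomes, and 0 by convention for a one-operon genome. This exact form is
this package's choice — the measure is described in the source literature
only as "an entropy of the genome" — and it is isolated behind
`modularity_score()` so an alternative can be swapped in.

### Choosing the weights

The two components live on different scales: $S_{\mathrm{mod}}$ spans a
range of 1 regardless of genome size, while a *single* misregulated gene
changes the mean-normalized $S_{\mathrm{exp}}$ by only $\mathcal{O}(1/|G|)$.
With $w_{\mathrm{exp}} = w_{\mathrm{mod}} = 1$ (the neutral API default)
the optimizer will happily destroy the expression of a few genes to gain
modularity — on a 40-gene test genome the *global optimum* of the equal-
weight objective collapses every regulated gene into one operon. Because
expression preservation is the design *constraint* and modularity only the
secondary objective, refactoring runs should use a penalty-scale weight:

$$w_{\mathrm{exp}} = 100\,|G|, \qquad w_{\mathrm{mod}} = 1,$$

which makes a 10% relative deviation on a single gene in a single
environment cost about as much as the entire modularity range, so only
expression-neutral rearrangements are profitable. This is the default in
the `refactor run` command line and in all refactoring examples below.

## The search

`anneal()` runs a population (default 10) of independent Monte Carlo
Simulated Annealing chains. Each chain starts from the genome in
*singleton-operon* form — every gene alone under its natural promoter —
which is the search's canonical starting condition; `start = "as_is"`
starts from the wild-type operon structure instead (the two conventions
coexist in the method's own description, so both are offered). Four moves
are proposed:

1. **move_gene** — a gene leaves its operon and is appended downstream of
   the destination's existing cistrons (upstream in genomic coordinates for
   reverse-strand operons), adopting the destination's effective
   regulation. Both primary promoters must be non-constitutive:
   constitutively driven genes are excluded from the design, since they
   could always be refactored trivially under a library of constitutive
   promoters. An emptied source operon is deleted.
2. **add_tandem** — a promoter from the tandem-candidate library is fused
   upstream (cap: three tandems per operon), adding its
   $(\alpha,\beta,\gamma)$ term. The cap counts *added* tandem promoters;
   the primary is not counted against it.
3. **remove_tandem** — the term is deleted; the primary promoter is never
   removable.
4. **replace_tandem** — one tandem's term is substituted by another
   candidate's.

Add/remove proposals are 10-fold more likely than replacements (defaults
0.60 / 0.18 / 0.18 / 0.036, renormalized). Actors are drawn uniformly among
valid choices; if the drawn move type has no valid actor the type is
resampled, and a genome with no legal move at all is an error.

Acceptance is the Metropolis rule for maximization: an improving or equal
candidate ($S_{\mathrm{new}} \ge S$) is always accepted, a worsening one
with probability $\exp((S_{\mathrm{new}} - S)/T)$. The temperature decays
exponentially, $T(n) = T_0 c^n$ with $c = 0.999$ per iteration and
$2 \times 10^4$ iterations by default. $T_0 = 0.1$ is calibrated to the
move scale of the recommended weighting: expression-neutral consolidations
gain $\sim 10^{-3}$, expression-breaking moves cost $\mathcal{O}(1)$ or
more, so $T_0 = 0.1$ tolerates marginal moves early while suppressing
catastrophic ones; a much hotter start lets early iterations scramble
expression faster than the iteration budget can repair, since repairs
require re-proposing specific (gene, operon) pairs. Each chain draws its
own RNG stream from the master seed; identical seeds give identical runs.

Every move record carries its inverse, and applying then undoing any move
restores the genome exactly — the property the audit trail and the
edit-level tests rely on.

## From network to nucleotide sequence

`compile_gtrn()` lays the genome down operon by operon, ordered along the
chromosome by the original locus of each surviving operon's primary
promoter (the method's own description never fixes a final layout; keeping
each operon at its promoter's native locus is this package's choice). Each
operon block, 5′→3′ on the coding strand, is

> tandem promoter regions (each followed by a fixed 20 bp isolation
> spacer) · primary promoter region · first-cistron RBS · ORF+TAA ·
> [RBS · ORF+TAA]… · terminator,

reverse-complemented into place for minus-strand operons. The rules:

* **Intergenic spacers are fixed sequence**: the promoter region, the
  first cistron's RBS and the upstream terminator travel unchanged through
  refactoring, so those regions are byte-identical between wild-type and
  refactored outputs wherever the operon survives.
* **RBS inference** (`infer_rbs()`): with a known transcription start and
  a 5′UTR of at least 15 bp, the RBS is the fragment from the +1 position
  to the base before the start codon; with an unknown start, the 60 bp
  immediately upstream of the start codon; with a 5′UTR shorter than
  15 bp, the UTR enlarged by an additional 60 bp upstream (total
  UTR + 60 — the literal reading of the enlargement rule). Leaderless
  5′UTRs are treated like any other.
* **Arriving genes lose their RBS**: every ORF arriving at the same
  destination operon receives the same RBS — the destination's
  first-cistron RBS by default, or a configured standardized sequence —
  matching the model's equal-expression-per-cistron assumption. Genes
  sitting in their native operon keep their native RBS (each gene records
  its `home_operon` for this purpose).
* **ORF preparation**: a TAA stop codon is appended to every ORF
  systematically, even when the ORF already ends in a stop, making each
  ORF a standalone rearrangeable module.
* **Opposite-strand overlaps** between an ORF and a promoter region are
  resolved by giving both operons an independent copy of the shared bases
  (`resolve_overlap()`); same-strand overlaps and overlaps swallowing an
  entire ORF are errors.

Output is a single-record FASTA plus a GenBank flat file with promoter,
RBS, CDS and terminator features. The regulatory parameters and the few
sequences not realized in the compiled genome (the native RBS of a
relocated gene, the region of an unused tandem candidate) travel in a
structured `COMMENT` block, so `parse_genome()` reconstructs the *exact*
genome: `parse(compile(g))` equals `g` structurally and
`compile ∘ parse ∘ compile` is byte-identical. Metadata is written in
sorted order so structurally equal genomes always serialize to identical
bytes.

## Evaluation metrics

* `complexity_ratios()` — $\Xi$, the refactored/wild-type ratio of
  regulatory-interaction counts, and $\Theta$, the ratio of operon counts.
  Interactions are counted at the operon level (operon × TF pairs with
  nonzero effective $\beta$), the granularity at which moves rewire the
  network; environmental ($\gamma$) edges are tallied separately and do
  not enter the headline $\Xi$.
* `optimality_degree()` — $\xi = S_{\mathrm{exp}}(\Delta v = 0) -
  S_{\mathrm{exp}}(\text{target})$: positive when the genome tracks the
  wild type worse in the target environment than at the optimum
  (sub-optimal adaptation), negative for over-optimality, exactly 0 in the
  optimal environment. `adaptation_report()` averages $\xi$ over an
  environment set.
* `functional_similarity()` — $\Phi_{op}$, the fraction of an operon's
  genes sharing its most common function label, 0 by convention for
  singleton operons (so every operon of the singleton starting condition
  scores 0). The function vocabulary is an input table; the default
  synthetic vocabulary has 184 labels.
* `topology_stats()` — genes and operons driven per promoter, the tandem
  count histogram, and the average clustering coefficient of the TF
  co-regulation projection (two TFs adjacent when both regulate some
  operon). The projection graph is this package's construction; TFs with
  fewer than two neighbours are counted as fully clustered (the
  vacuous-truth convention), so two TFs that co-regulate everything score
  1 rather than NaN.

## Synthetic study systems

`generate_gtrn()` builds genomes with the structure the method assumes, so
every stage is testable without external data:

* singleton operons, one natural promoter per gene, random ACGT parts
  (ORFs start with ATG, have clean stop-free bodies and length divisible
  by 3; 60 bp RBSs; 40 bp promoter regions; 30 bp terminators);
* a TF fraction near 330/4298 ≈ 7.7% and category tags covering
  TF/enzyme/stress/defense, emulating the scale of an enterobacterial
  genome model;
* **redundancy**: promoters come in groups of `redundancy` (default 5)
  sharing a *verbatim-identical* regulatory function. A 100-gene genome
  with redundancy 5 therefore has a known ground truth — consolidation to
  20 promoter groups (less the constitutive ones, whose genes cannot
  move) with bitwise-unchanged expression — which is the
  parameter-recovery surface the annealing tests measure against;
* $\delta \sim \mathrm{LogUniform}(0.1, 2)$ h⁻¹ (no distribution is given
  by the method's source; this spans typical bacterial mRNA half-life
  scales);
* stability by construction: $\beta$ coefficients are globally rescaled so
  every promoter's $\sum|\beta|$ stays below $0.2\,\min\delta$, making
  $D - B$ strictly diagonally dominant — hence nonsingular and stable —
  for *any* operon assignment and any stack of up to three tandem
  promoters. A spectral-abscissa condition on the starting genome alone
  would not survive rearrangement.

`generate_environments()` reproduces the perturbation designs used to
probe adaptation: oxygen uptake drawn uniformly from fully anaerobic to
4-fold the optimal flux of 75 mmol g⁻¹ h⁻¹; glucose uptake from −20 to
+20 mmol g⁻¹ h⁻¹ around an optimum of 20; or joint perturbation of all
factors with every deviation nonzero. The optimal environment
($\Delta v = 0$) is always element 1. Deviations are passed to the model
raw, without clipping at environment boundaries.

What these synthetic systems do *not* emulate: real expression
distributions, real operon length distributions, sequence-level promoter
biology, or curated regulatory-database content. Passing tests demonstrate
the correctness and recoverability properties of the algorithms, not
biological claims about any real genome.

## A worked refactoring run

```{r run, eval = FALSE}
g <- generate_gtrn(synthesis_spec(n_genes = 100, redundancy = 5, seed = 1))
envs <- generate_environments("multi", n = 4, seed = 5)
spec <- fitness_spec("all", envs,
                     weight_expression = 100 * length(g$genes),
                     weight_modularity = 1)
sch <- annealing_schedule(t0 = 0.1, iterations = 20000,
                          population = 10, seed = 1)
res <- anneal(g, spec, sch)
res
```

At these settings all ten chains consolidate the 100 singleton operons to
37 — the 16 non-constitutive promoter groups collapse into multi-gene
operons while the 20 constitutive singletons cannot move — with the
expression score at floating-point zero, in roughly three to four minutes
on one CPU. The test suite runs the same
experiment with single-chain seeds 1–10; problem sizes throughout the
suite (genomes of 5–100 genes, environment sets of 2–5, walks of a few
thousand proposals) were chosen so the whole suite completes in minutes
while still exercising genome-scale code paths.

## Known limitations

* Regulation is linear; saturation, cooperativity and Hill-type responses
  are outside the model, as are translation rates, protein dynamics and
  stochastic expression noise.
* Tandem promoters combine perfectly additively; transcriptional
  interference between stacked promoters is a recognized biological
  caveat, not modelled here.
* The entropy modularity measure and the TF-projection clustering
  construction are stand-ins where the method's source delegates or leaves
  the definition open; both are isolated behind single functions.
* The compiler preserves sequence information but performs no codon
  re-optimization, repeat screening, or terminator-strength engineering.
* Whether the three-tandem cap should count the primary promoter is
  ambiguous in the method's description; it is implemented as three
  *added* tandems.
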