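---
title: "Models and methods: opsin pseudogenes, spectral tuning, and dN/dS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: opsin pseudogenes, spectral tuning, and dN/dS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinevol)
```

opsinevol analyses the molecular evolution of vertebrate visual opsin coding
sequences on a phylogeny. Its stages mirror how a cone-opsin data set is
actually worked up: call each sequence functional or pseudogenised from its
ORF lesions; read the spectral phenotype off a handful of key residues;
quantify selective pressure with codon models; date when dead copies stopped
being constrained; and ask whether lineages converged at the protein level.
Every stage can be exercised against simulated data with known ground truth,
which is how the package tests itself.

## The fitted-model core: Goldman–Yang codon models

The central object is a maximum-likelihood fit of a codon substitution model
(`fit_codon_model()`). The generator over the 61 sense codons has entries

$$q_{ij} \propto \pi_j \,\kappa^{\mathrm{ts}(i,j)}\, \omega^{\mathrm{N}(i,j)}$$

for codons differing at one position (zero otherwise), where $\kappa$ is the
transition/transversion rate ratio, $\omega = d_N/d_S$ scales nonsynonymous
changes, and $\pi_j$ are codon equilibrium frequencies (`F1x4` by default,
estimated from the data; `F3x4` and uniform are selectable). Each generator
is rescaled so one unit of branch length is one expected substitution per
codon site; for site-mixture models the rescaling uses the mixture-average
rate so branch lengths keep a single meaning across classes.

Supported parameterisations: `M0` (one $\omega$), `two_ratio`
(foreground/background, with the foreground defined by branch tags from an
annotation table via `label_branches()`, by tip sets, or by node ids),
`free_ratio` (one $\omega$ per branch — intended for small trees only; its
parameter count grows with the tree), and the site mixtures `M1a`, `M2a`,
`M7` (beta, discretised into `ncat = 10` equal-probability categories) and
`M8` (beta plus a class with $\omega_s \ge 1$). Nested pairs are compared
with `lrt()`, using $2\Delta = 2(\ln L_1 - \ln L_0)$ against a
$\chi^2$ upper tail (M0 vs two-ratio: 1 df; M1a/M2a and M7/M8: 2 df).

Likelihoods come from Felsenstein pruning over compressed site patterns,
with per-pattern log scaling against underflow. Optimisation alternates
bounded quasi-Newton (`L-BFGS-B` on log/logit-transformed parameters) over
the substitution parameters with Brent line searches on each branch length;
the one-branch profile uses cached inside *and* outside partials, so a
profile evaluation costs a single matrix product. Convergence is declared at
a log-likelihood improvement below `tol` (default `1e-8`); non-converged
fits carry a warning flag rather than failing silently. Three deterministic
starts (spread around the initial values, all recorded in `$starts`) guard
against local optima; heavy simulation experiments in the test-suite use
one start, which pilot runs showed to be sufficient at those data sizes.
Parameter bounds follow common practice: $\omega_s \in [1, 50]$, beta
$p, q \in [0.005, 99]$.

Two deliberate scope choices: Bayes empirical Bayes site identification is
not implemented (the per-site class posteriors that `M2a`/`M8` could expose
are naive empirical Bayes and are not labelled otherwise), and branch
lengths can either be re-optimised under every model (default, appropriate
for small data) or fixed at input values, the common practice when an M0
tree is estimated first.

The ML-free cross-check is `count_dnds()`, a Nei–Gojobori (1986) counting
estimator: synonymous site fractions per codon position with mutations to
stops excluded, multi-nucleotide codon differences averaged over minimal
stop-avoiding pathways, and Jukes–Cantor correction of the proportions. On
low-divergence pairs it agrees with the M0 MLE to well within $\pm 0.1$.

## ORF integrity and lesion placement

`scan_orf()` compares every row of the alignment to a designated reference
row (by default the first gap-free, internally stop-free sequence — the
reference may legitimately carry gap columns opposite other taxa's
insertions). Indel polarity is defined relative to that reference; maximal
gap runs are reported one lesion each, never merged across intervening
bases. Premature stops are found in each sequence's *own* reading frame —
reading the degapped sequence from its start makes the frame shift
downstream of any frameshifting indel automatically. A sequence is a
pseudogene when it carries a frameshifting indel or a disqualifying
premature stop. The terminal stop is never a lesion, and stops in the final
10% of the ORF are reported but tolerated by default (C-terminal truncations
can retain function); both the window and whether it flips the call are
configurable, because real data sets contain judgement calls either way.
`check_splice_sites()` applies the GT/AG rule to exon-interval annotations.

`place_lesions()` puts each distinct lesion signature (kind, codon column,
length) on the branch above the most recent common ancestor of its carriers
— Dollo parsimony, a single gain and no reversal, which is the natural model
for a shared disabling mutation. If that clade contains non-carriers the
signature is flagged homoplastic and left tip-assigned rather than silently
forced onto one branch.

## Spectral tuning

For LWS/MWS pigments the wavelength of peak absorbance is read from the
five key residues 180, 197, 277, 285 and 308 in bovine rhodopsin numbering.
Numbering is transferred by global BLOSUM62 alignment to the bundled bovine
rhodopsin reference (UniProt P02699; swappable, and documented as such),
with an identity floor of 15% below which an empty map is returned rather
than nonsense coordinates. The shipped lookup table pins four exact
haplotype assignments — SHYTA 560 nm, AHYTA (S180A) 555 nm, SHYAA (T285A)
543 nm, AHYAA 536 nm. An additive fallback (per-substitution shifts, e.g.
S180A −5 nm, T285A −17 nm, with H197Y −28, Y277F −8 and A308S −27 taken as
approximate values from the classical tuning literature) covers unseen
haplotypes and is always flagged `additive` in the provenance column. The
exact table takes precedence because the published combined-substitution
value (536 nm) is not the additive sum of the single-substitution shifts —
additivity is an approximation, not an identity.

SWS1 pigments are classified UV (~360 nm) versus violet/visible (>400 nm)
from site 86, the dominant determinant: phenylalanine gives UV; any other
resolved residue gives violet/visible, a literature extrapolation that the
output flags. Sites read through gaps or ambiguity codes become `?` and are
reported unresolved rather than guessed; an unresolved site 86 yields a null
classification. The 11-site SWS1 set (46, 49, 52, 86, 90, 93, 97, 113, 114,
116, 118) is configuration, not code, since site inventories differ between
studies.

## Ancestral states and convergence

`fitch_parsimony()` is the standard two-pass algorithm with missing tips
excluded from scoring; ambiguous nodes carry their full state set, and a
deterministic representative (parent state if possible, else alphabetical)
makes downstream event lists reproducible. `marginal_ml_reconstruction()`
computes exact marginal posteriors per node and site by the inside–outside
algorithm under a uniform-rate Poisson model by default — with a pluggable
reversible generator — reusing the same pruning engine as the codon
likelihoods. The Poisson default is deliberate: for the short amino-acid
distances involved here the reconstruction is dominated by the data, and a
parameter-free model keeps the stage free of hidden tuning.

`enumerate_substitutions()` emits one event per branch and site where the
parent and child representatives differ; `detect_convergence()` then
classifies sites changed on both members of a branch pair as convergent
(same derived state) or divergent (different derived states). Nested branch
pairs are rejected: comparing a branch with its own ancestor would count the
same history twice.

## Dating loss of constraint

The sudden-relaxation model assumes a lineage evolves under its usual
constraint $\omega_f < 1$ until some moment, after which constraint is
completely gone ($\omega = 1$). Because synonymous substitutions accumulate
at the same rate in both eras, the dN/dS observed over a branch of duration
$T$ My that lost constraint $T_p$ My ago is the time-weighted mixture
$\omega_m T = \omega_f (T - T_p) + T_p$, hence

$$T_p = T\,\frac{\omega_m - \omega_f}{1 - \omega_f}.$$

`categorize_branches()` first classes branches around lesion origins
(functional / premutation / mixed / nonfunctional); `resolve_mixed()` then
applies the equation to each mixed branch, with $\omega_f$ from the
functional category, $\omega_m$ from the mixed branch's own estimate, and
$T$ from the calibrated time tree (node ages are inputs; no divergence-time
estimation is attempted here). Estimates outside $[0, T]$ — expected under
sampling noise near the limits — are clamped and flagged, never hidden.
When a fully nonfunctional era exists below the mixed branch its
$\hat\omega$ is only a diagnostic (it should be near 1); dating always uses
the mixed branch, because the nonfunctional era contains no information
about *when* constraint was lost. Where two defensible dating routes exist
(the equation on a single branch versus category-resolved estimates) both
are reported side by side rather than merged.

## The simulator: what it emulates and what it does not

`simulate_codon_alignment()` evolves codon sequences by exact event-by-event
(Gillespie) sampling from the same generator family the fits use, with
branch-specific $\omega$, recording every substitution. Identical seeds give
identical output. `simulate_pseudogenization()` adds the loss process: on a
time tree (My), lineages evolve under background $\omega$ until their stated
loss age, then switch to a neutral chain on all 64 codons in which changes
into and out of stop codons are neutral — a dead pseudogene accepts stops.
Both eras are scaled to the same neutral clock (`rate`, default 0.005
substitutions per codon site per My, a typical mammalian nuclear rate of
order $1.7\times10^{-9}$/nt/yr), which is exactly the assumption the dating
equation rests on. If a dead lineage reaches its tip with no stop codon, one
codon in the 5' 80% of the ORF is rewritten to TAA and recorded — the
scanner needs a lesion to find, and a tolerated C-terminal stop would not
represent a disabled gene.

What the simulator does *not* emulate: indel evolution (lesions are
injected, not evolved), rate heterogeneity beyond branch-$\omega$, selection
on codon usage, alignment error, and sequencing artefacts. Passing the
recovery experiments therefore demonstrates the estimators are correct and
calibrated under the stated model, not that real opsin alignments satisfy
that model.

Two 12-taxon presets (`opsin_preset()`) bundle an ultrametric 40-My tree
with one high-duty-cycle echolocator clade, cave-roosting lineages and diet
tags, mirroring the contrast groups of a bat-opsin style analysis; they are
labelled synthetic throughout.

## Numerical choices and problem sizes

Transition probabilities come from a symmetrised eigendecomposition of the
reversible generator (exact for these matrices, and cheap to re-evaluate at
many branch lengths); pruning partials are rescaled per pattern with log
accumulators. Ambiguity is always propagated (`X`/`?`), never imputed. Codon
columns containing a gap, stop, or ambiguous codon in any sequence are
removed before fitting, with a removal log attached.

The test-suite's simulation experiments use sizes chosen as the smallest at
which the pilot behaviour is stable: M0 recovery at 16 taxa x 500 codons
(tolerance $\pm 0.05$ on $\hat\omega$); foreground/background ordering at
8 taxa x 500 codons over 50 replicates; dating recovery with a loss halfway
along a 20-My terminal branch at 800 codons over 20 replicates, judged on
the median recovered $T_p$ (a bias criterion — single-branch $\omega$
estimates are individually noisy at realistic substitution counts, and the
median over replicates is what a recovery experiment can promise).

## Known limitations

* `free_ratio` is practical only on small trees; nothing prevents you from
  fitting it on 100 taxa, but the optimiser dimension makes that unwise.
* The additive lambda-max fallback inherits the uncertainty of its published
  shift values; exact entries should be added for haplotypes of interest.
* The dating equation attributes the whole $\omega$ elevation on a mixed
  branch to sudden, complete relaxation; gradual relaxation or partial
  constraint loss will bias $T_p$ toward the present.
* Branch categories depend on lesion placement; homoplastic lesions are
  excluded from origins rather than resolved.

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(list(seed = 4, outdir = "run1"))
report
```

The pipeline writes TSVs (lesions, functionality calls, tuning profiles,
model fits, branch categories, loss dates, convergence report) plus the
simulated inputs, and returns a per-stage report with a checksummed
manifest; identical config and seed give byte-identical outputs.
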