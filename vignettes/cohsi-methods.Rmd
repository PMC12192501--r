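---
title: "Canonical equilibrium distributions of discrete token systems"
author: "cohsi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical equilibrium distributions of discrete token systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohsi)
```

## The model

A discrete system is a collection of components each assembled from
distinguishable pieces: a protein is an ordered string of amino acids, a C
function an ordered stream of lexical tokens, a word-count table an
unordered set of boxes of identical beads. The package treats two conserved
quantities over the ensemble of all systems of the same size: the total
size $T = \sum_i t_i$ and the total Hartley–Shannon information
$I = \sum_i t_i I_i$, where the information of a message of $N$ symbols
over a unique alphabet of $P$ equally likely symbols is $N \ln P$ — the log
of the number of possible arrangements, requiring only distinguishability
and no intrinsic meaning. Maximising the multinomial weight
$\Omega = T! / \prod_i t_i!$ subject to the two constraints, with
Ramanujan's factorial approximation
$$\ln t! \approx t \ln t - t + \tfrac{1}{6}\ln(t + 4t^2 + 8t^3)
  + \tfrac{1}{2}\ln \pi$$
supplying a continuous, accurate continuation of the factorial, gives the
stationarity condition
$$\ln t_i + \frac{1 + 8 t_i + 24 t_i^2}{6 (t_i + 4 t_i^2 + 8 t_i^3)}
  = -\alpha - \beta \frac{dI_i}{dt_i}.$$
The left-hand side is `occupancyGradient()`; it equals $\ln t$ plus a
droop term bounded by $33/78$ that decays like $1/(2t)$. $\alpha$ purely
normalises; $\beta$ is the power-law slope magnitude. Two variants follow
from the information functional:

* **Heterogeneous** (ordered strings): $dI_i/dt_i = \ln a_i$ with $a_i$
  the category's unique alphabet size, treated as a fixed category
  parameter. The solution is a power law in the category value with a
  sharp feasibility-limited onset — a string cannot contain more distinct
  symbols than its length, so categories with predicted occupancy below
  their alphabet are clipped to zero (`canonicalProfile()` with the
  feasibility clip).
* **Homogeneous** (unordered categories): the same equation with the
  category value a rank or multiplicity class. The solution is Zipf-like
  with a droop in the least-populated bins, because the $1/(2t)$
  correction bites exactly where $t$ is small.

Occupancies are real-valued: the stationarity condition is derived by
continuous variation, so the solvers work in the continuous relaxation
and integers appear only at sampling or reporting time. Categories whose
right-hand side falls below $33/78$ (occupancy under one component) are
reported as unoccupied rather than as errors; this is what gives the
solutions finite support and a finite maximum length at any system size.

## Inverting the gradient

`solveOccupancy()` inverts the gradient by bracketed Brent iteration on
$[1, t_{hi}]$ with $t_{hi}$ doubled until the gradient exceeds the target,
to relative tolerance $10^{-10}$, plus one Newton polish. Profile builders
use a vectorised fixed-point iteration $t \leftarrow e^{\,\mathrm{rhs} -
g(t)}$ (the droop $g$ is a contraction) followed by Newton steps; the two
routes agree to $10^{-10}$ and are cross-checked in the tests.
`normalizeTotal()` adjusts $\alpha$ alone until $\sum_i t_i$ hits the
requested total to relative $10^{-8}$, by monotone bracketing. Because the
stationarity condition contains no reference to $T$, the normalised shape
$t_i/T$ is scale-independent — exactly so for the pure power-law envelope,
and up to a finite-size correction of order $1/(2 t_i)$ per category where
occupancies are small. The property test therefore checks pointwise
$10^{-6}$ shape invariance at totals large enough ($T \ge 10^{12}$ over
100 categories) that every category is well occupied; at small $T$ the
droop makes the shape weakly scale-dependent, which is a genuine
finite-size effect, not numerical error.

## The brute-force ensemble oracle

For small systems the canonical solution can be checked against exact
enumeration: `enumerateCompositions()` lists every occupancy vector of
$T$ into $M$ categories (guarded at $10^7$ compositions),
`multinomialWeight()` evaluates $\Omega$ in exact integer arithmetic (a
small base-$10^7$ limb representation, so values stay exact far beyond
$2^{53}$; weights up to $T = 60$ are exact, log-space is used for
anything larger), and `modalComposition()` finds the maximal-weight
composition, with near-ties resolved by exact comparison and genuine ties
reported in full. The information constraint is enforced as a tolerance
band — integer compositions rarely hit a real-valued target exactly — with
the default width half the smallest category information increment.
`compareToCanonical()` closes the loop: the deviation of the enumerated
modal composition from the normalised canonical solution shrinks as $T$
grows with the constraint shape held fixed (the tests compare $T = 30$
against $T = 300$ at $M = 3$), which is the sense in which the canonical
solution is the overwhelmingly most likely configuration.

## Corpus measurement

`readFasta()` (via Biostrings) and `readUniprotFlat()` convert protein
corpora to component records: length, unique-alphabet size, content
identity, species label. Sequences are uppercased first — case is
formatting, not content — and non-standard residue codes (B, Z, X, U, O)
are kept as distinguishable symbols, since Hartley information requires
distinguishability only. Content identity is the normalised sequence
string itself rather than a lossy hash: grouping is then exact by
construction, matching the definition of protein multiplicity as exact
equality in both number and sequence of amino acids. Species identity
defaults to the OS line text (continuation lines concatenated, terminal
period trimmed) with the OX taxon id as fallback; both are supported
because published multiplicity counts do not state which was used.

`tokenizeC()` lexes ISO C90/C99 by maximal munch with a single ordered
alternation: comments and whitespace are discarded, and every surviving
character belongs to exactly one token. Token identity is the exact
spelling (`0` and `0x0` differ). Preprocessor directives are tokenized
(directive as one token, payload as ordinary tokens) and included in
frequencies — one consistent, testable rule, since whether published
token counts included preprocessor tokens is unstated. No macro
expansion and no `#include` following: the measured quantity is the
written token stream. `extractFunctions()` recognises
`identifier ( ... ) {` at brace depth zero; K&R-style definitions are out
of scope and yield no span.

## The two-stage power-law verdict

A straight line on a log–log plot is only a necessary condition.
`olsLogLog()` implements it (ordinary least squares of $\ln$ ccdf — or
$\ln$ count — on $\ln$ value over a stated region, with the standard
small-sample adjusted $R^2$); `fitDiscretePowerLaw()` plus
`bootstrapGoF()` implement sufficiency: a discrete, Hurwitz-zeta
normalised maximum-likelihood fit and a semiparametric KS bootstrap in
which each replicate resamples the below-cutoff body empirically, draws
the tail from the fitted law, refits, and records its KS statistic. The
p-value is exactly the fraction of replicate statistics at least as large
as the observed one; $p > 0.1$ means power-law behaviour cannot be
rejected. A rejection is annotated as possibly out of equilibrium:
conservation of information is a weak constraint (typical $\beta < 4$,
against $\beta \sim 10^{21}\,\mathrm{J}^{-1}$ for energy), so departures
from equilibrium are expected and are never read as a
counter-demonstration. Comparison against alternative heavy-tailed
families is deliberately not implemented: with an underlying theory in
hand, non-rejection is the relevant question.

Numerical choices: the Hurwitz zeta is evaluated by Euler–Maclaurin
summation (16 direct terms, Bernoulli corrections through $B_6$),
cross-checked against direct series summation to $10^{-10}$ across
exponents 1.1–5; the MLE maximises over exponents in $(1, 25)$ by Brent
search to $10^{-9}$; discrete sampling uses an inverse-CDF lookup table
with exact bisection beyond the table, so draws are exact, not capped.
All integer data use the discrete law throughout — lengths,
multiplicities and token counts are integers, and the continuous
approximation is avoided.

Two range conventions matter in practice. First, when an analysis
prescribes a fixed fit region, the sufficiency fit takes the region's
lower edge as its cutoff and, where the region (or the data) has a hard
upper bound — a multiplicity can never exceed the number of species — the
law is renormalised on the bounded support (`xmax`); testing bounded data
against the unbounded law would reject for the truncation rather than
the shape. Second, `populatedRange()` restricts the necessary test to
categories holding at least ten observations: log–log least squares over
nearly empty categories measures Poisson noise, not shape. At full corpus
scale this reproduces published fit regions (multiplicities up to
thousands); at desk scale it adapts to the synthetic corpus size.

## Synthetic corpora: what they emulate, and what not

The generators produce corpora with the statistical structure the
analysis assumes, so every pipeline stage is testable offline, and every
sampled value is recorded in a ledger so that downstream measurements can
be validated by exact bookkeeping equalities before any statistics enter.

`genHeterogeneousCorpus()` samples lengths by inverse CDF from the exact
discrete canonical law with pmf $\propto t(\ell;\alpha,\beta{+}1)$ on
$[\ell_{peak}, \ell_{max}]$, so the measured ccdf tail slope is
$-\beta$. This aggregation — category value read as length, slope
$\beta + 1$, support floored at the feasibility onset — is this package's
own construction: the derivation that maps per-alphabet occupancies into
the observed length distribution below the feasibility line is published
only in work we could not obtain, so the generator encodes the
operational consequences (sharp unimodal peak at the onset, exact
power-law tail of the prescribed slope, finite maximum length set by the
unit-occupancy condition) rather than a derived closed form. Defaults
emulate the protein corpus: peak near 300 residues, tail slope 3.1,
support bounded by the unit-occupancy length at 45,000 — the order of the
longest known protein. What it does **not** emulate: the smooth rise of
the real pdf below its peak, biologically realistic sequence content
(codon bias, domains), and any correlation between a component's length
and its species. Passing recovery tests therefore show that the fitters
recover a known law through the full pipeline, not that real corpora obey
it.

`genMultiplicityFasta()` draws group multiplicities from either a pure
Zipf law or the canonical drooping law, truncated at the species count
(a multiplicity cannot exceed it; truncation is the bulk form of the
resample-and-log rule), and replicates each group's sequence into that
many distinct synthetic species. `genCLikeSources()` emits lexable
function definitions whose statement identifiers follow a Zipf law of
configured slope over a fixed vocabulary; the structural scaffolding
(keywords, punctuation, function names) is deterministic, so recovery is
assessed on the vocabulary tokens the ledger defines. Generator output is
byte-deterministic in the seed.

## Problem sizes and stability of the desk-scale checks

The acceptance-level checks in this package run at sizes a laptop
handles in minutes, chosen once as realistic desk-scale analogues:
$10^5$ components for the heterogeneous recovery (tail slope within
$\pm 0.15$ of 3.1 over the 400–20,000 region), $3\times 10^4$ groups
over 200 species for multiplicity (slope within $\pm 0.1$ of 1.33),
$10^6$ tokens over a 5000-word vocabulary (slope within $\pm 0.1$ of
1.19), and $10^4$ against $10^6$ components for scale independence.
Bootstrap operating characteristics use 20 datasets of $n = 2000$ with
200 replicates per class.

For cross-version slope comparisons the fit region defaults to the part
of the support jointly dense in all versions — from just above the common
onset to the 95th percentile of the smallest version. A version of $10^4$
components determines a tail slope to about $\pm 0.03$ at best (the
information bound $(\hat\alpha - 1)/\sqrt{n}$); including sparsely
populated abscissae, where singleton observations dominate, inflates that
several-fold. The dense-region rule keeps the comparison inside the
regime where the slope difference reflects the law rather than sampling
noise; even so, the $< 0.05$ stability bound sits within a factor of two
of the sampling floor, and an occasional seed will exceed it.

## Known limitations

* The energy-constrained branch of the formalism (temperature,
  Boltzmann's closure to classical entropy) is outside scope; only the
  information-constrained branch is implemented.
* The heterogeneous length aggregation below the feasibility line is the
  package's own operational construction, as discussed above.
* The lexer is purely lexical: digraphs/trigraphs, C++/Objective-C and
  K&R definitions are unsupported; files relying on them yield fewer
  spans.
* Full-scale corpora (the multi-hundred-GB protein releases, tens of
  millions of lines of C) are read by the same streaming-friendly
  interfaces but are not exercised in the test suite; the largest corpora
  tested are the synthetic ones above.
* Monte-Carlo sampling of large constrained ensembles is not provided;
  the ensemble oracle is enumeration-only, guarded at $10^7$
  compositions.
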