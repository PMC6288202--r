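---
title: "Phenotype-driven rare-disease ranking: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven rare-disease ranking: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodx)
```

## The problem

A clinician suspecting a rare disease typically holds a list of observed
phenotypes — standardized terms from an is_a-structured ontology of
phenotypic abnormalities — and needs a short, ordered list of candidate
diagnoses. `phenodx` implements the full pipeline for this task: an
ontology layer (parsing, ancestor closures, information content, MICA),
a disease–phenotype knowledge base, four ranking models sharing one
score combiner, the top-k evaluation methodology, and a synthetic-data
generator so everything is testable offline.

## Information content and term weighting

All models rest on annotation information content. For term $t$,

$$\mathrm{freq}(t) = \#\{d : t \in \mathrm{closure}(P(d))\}, \qquad
  \mathrm{IC}(t) = -\ln\frac{\max(\mathrm{freq}(t), 1)}{N}$$

where $P(d)$ is disease $d$'s annotation set, $\mathrm{closure}$
propagates to all is_a ancestors, and $N$ is the number of diseases.
This is the standard Resnik construction; propagation guarantees
$\mathrm{IC}$ is non-increasing from child to parent, which the test
suite asserts on random DAGs. Two deliberate choices:

* **Log base.** Natural log. Nothing downstream depends on the base
  (scores are normalized before combination), so we use nats.
* **Zero-frequency floor.** Unannotated terms get
  $\mathrm{freq} = 1$, i.e. the rarest observed level, instead of
  infinite IC. Query terms are frequently unannotated in the corpus and
  must remain scorable and finite.

The **TF-IDF-Hierarchy** weight of term $t$ for disease $d$ is
$\mathbf{1}\{t \in \mathrm{closure}(P(d))\} \cdot \mathrm{IC}(t)$:
ancestor propagation is the Hierarchy step, binary presence is the TF
step, and IC plays the corpus-rarity (IDF) role. The weighting scheme
this name refers to in the literature is not defined operationally
anywhere we could rely on, so this package fixes the construction above
and documents it as its own reading; it is the natural composition of
the three ingredients, and the identity "query with a disease's exact
annotation set $\Rightarrow$ the disease's own weight row" (tested)
makes the scheme self-consistent. The vocabulary keeps every term with a
nonzero weight for at least one disease; the root (IC 0) never enters
it.

## The four ranking models

**PICS** scores every candidate with four classifiers: cosine and
Tanimoto similarity between the IC-weighted query and disease vectors;
the set-mismatch score $\Psi = 1 - n/\max(|Q|, |P(d)|)$ with $n$ the
symmetric-difference size; and symmetric best-match MICA similarity

$$S(Q \to D) = \mathrm{avg}_{q \in Q} \max_{p \in D}
  \mathrm{IC}(\mathrm{MICA}(q, p)), \qquad
  S_{\mathrm{sym}} = \tfrac12 S(Q \to D) + \tfrac12 S(D \to Q).$$

Three numerical choices here. (1) $\Psi$ can go negative for disjoint
sets; we clamp to $[0,1]$ so all four classifier scores stay
commensurable before averaging. (2) The source description of the
directed similarity names one direction while summing over the other;
since only the symmetric version enters ranking, the orientation
ambiguity is immaterial — we define directed(from→to) as averaging over
`from`. (3) For combination the MICA score is divided by the maximum
vocabulary IC so it lives in $[0,1]$ like the others; the raw value
stays available through `mica_similarity_*`.

**PGAS** replaces term IC with gene evidence: each phenotype term is a
binary incidence vector over the genes associated with it, phenotype
pairs are compared by cosine or Tanimoto, and query and disease term
sets are combined by the same symmetric best-match average. Gene vectors
are unweighted because no principled gene weighting is available at the
phenotype level.

**CPML/APML** treat diagnosis as multi-class classification. Training
data are simulated patients: for each disease, each annotated term is
kept with probability $1 - \mathrm{dropout}$ and
$k \sim \mathrm{Poisson}(\lambda)$ noise terms are added uniformly from
the rest of the term universe. The full-scale corpus ratio is 10
patients per disease; defaults are dropout 0.2 and $\lambda = 2$,
chosen once as a realistic imprecision level (roughly one in five
findings missed, about two incidental findings per record) — the
original corpus documents only the patient count, not the sampling
scheme, so this is this package's stated world. Features are the same
IC-weighted propagated vectors as PICS queries. The six classifiers are
logistic regression (glmnet ridge multinomial), kNN (FNN,
inverse-distance votes), Bernoulli naive Bayes, random forest, extra
trees, and a one-hidden-layer neural network (`min(256, p)` tanh units,
full-batch Adam). The forests exploit a structural fact: every feature
column takes only the values $0$ and $\mathrm{IC}(t)$, so the exhaustive
Gini split search reduces to binary presence splits — the native
implementation is exact, not an approximation. Extra trees differ by
dropping the bootstrap and halving the candidate-feature count per
split.

## Bayesian averaging

Each classifier's score vector is min–max rescaled and sum-normalized to
a distribution; members are combined as $\sum_i w_i p_i(d)$ with
non-negative weights normalized to 1. Min–max before sum-normalization
(rather than softmax) preserves every member's internal ranking and
introduces no temperature parameter. For the ML models the member
weights are validation top-1 accuracies on a stratified split (uniform
when no validation split is requested); the "Bayesian averaging"
terminology in this field is used loosely and no priors or marginal
likelihoods are specified anywhere, so accuracy weighting is our
concrete, documented reading, with the uniform fallback available.

Ties in every ranking break on the lexicographically smallest disease
id (C collation), making all outputs bit-reproducible.

## Evaluation conventions

A record is a true positive at cutoff $k$ if the truth is among the $k$
highest-ranked candidates, a false positive if the model predicted but
missed, and a false negative if the model **abstained** — emitted no
positively scored candidate. This abstention reading is the only way
"precision near 1 with materially lower recall" can coexist with the
standard TP/FP/FN formulas, since without abstentions every record is
TP or FP and precision equals recall. F1 is the standard harmonic mean;
a printed source formula with a doubled denominator is treated as a
typographic corruption (it would yield 0.19 where 0.73-0.76 is
reported).

The ranking distribution reports `top1`, cumulative `top10`, `other`
(rank > 10) and `unranked`. Because `top10` includes `top1`, the
sum-to-one identity holds for the exclusive partition
`top10 + other + unranked`.

Query-size sensitivity subsamples each record's terms uniformly without
replacement (seeded) at each requested size and re-scores; the
acceptance suite checks over 20 seeds that one-term queries never beat
full queries on mean F1 — the qualitative shape reported for this family
of models, whose sweet spot is around 15 input terms.

## The synthetic world, and what a green test does not establish

The generator emulates the shapes that matter: a rooted is_a DAG built
level by level (second parent with probability 0.2, so diamonds exist
and MICA is non-trivial); leaf-biased annotation sampling
($\Pr \propto 1/(1+\#\mathrm{descendants})$, mirroring the practice of
annotating specific terms); a gene map with a shared pool; and cohorts
with dropout/noise, optionally tuned so the expected record size matches
a target (e.g. 17 terms, the mean symptom count of real metabolic-EMR
records). Desk-scale defaults — 300 terms, 50 diseases, 5–12 terms per
disease, 200 genes — exercise sparsity in seconds.

What it does **not** emulate: real nosology (diseases here are
independent draws, whereas real rare diseases cluster into phenotypically
overlapping families), ascertainment bias in EMR phenotyping,
inter-disease annotation correlation, or corpus-scale class imbalance.
Green acceptance tests therefore establish correctness of the
machinery and sane statistical behaviour under the stated world — not
the headline clinical accuracy of any production deployment, which was
measured against external records and data snapshots that are not
redistributable.

## Degenerate inputs and numerical edges

Zero vectors score 0 under cosine and Tanimoto; empty term sets are
input errors; multi-root term pairs with no common ancestor get the
sentinel MICA (no term, IC 0); constant score vectors normalize to the
uniform distribution; patients losing every term to dropout get one
annotated term back; a backend that fails to train is dropped with a
warning and the ensemble renormalizes. All randomness flows through
per-call seeds derived from a user seed via a 32-bit hash, and library
code always restores the caller's RNG state.

## Known limitations

* Only is_a edges are traversed; other relationship types are ignored.
* PGAS is insensitive to gene dosage or weighting; tied gene profiles
  are common in small gene maps.
* The ML models cannot rank a disease absent from training labels —
  diseases with no exposed phenotypes are dropped from the candidate
  set by construction.
* The deep-network backend is deliberately small; it exists to satisfy
  the six-classifier contract at desk scale, not to be competitive at
  corpus scale.
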