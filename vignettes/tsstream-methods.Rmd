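---
title: "Velocity-based word similarity: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-based word similarity: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsstream)
```

## The measure and its assumptions

`tsstream` estimates the similarity of two terms at a point in time from
the *rates* at which messages containing them arrive. For a term $w$ and a
reference time $t$, take the timestamps $\tau_1 \le \dots \le \tau_M$ of
the last $N$ messages at or before $t$ that contain $w$. The rate estimate
is the inverse mean inter-arrival time,
$$\hat\Phi(w) = \left[\frac{1}{N-1}\sum_{i=1}^{N-1}(\tau_{i+1}-\tau_i)\right]^{-1}
             = \frac{N-1}{\tau_N-\tau_1},$$
where the second form follows because the sum telescopes — the estimator
depends on the window only through its first stamp, last stamp and count.
The joint rate $\hat\Phi(w_1 \wedge w_2)$ is computed identically from
messages containing *both* terms (in any order, counted once per message).
The similarity is
$$\mathrm{TSS}(w_1, w_2) =
  \left[\frac{\hat\Phi(w_1\wedge w_2)}{\max(\hat\Phi(w_1),\hat\Phi(w_2))}\right]^{\alpha}.$$

The underlying population quantity is a conditional co-occurrence
probability: if messages arrive as a Poisson process and term inclusion is
i.i.d. across messages, the ratio of true rates is
$P(\text{both} \mid \text{the more frequent one})$, so the measure is a
normalised co-occurrence akin to a confidence/overlap coefficient, made
*local in time* by the last-$N$ window. The exponent compresses the heavy
left tail of small ratios onto a readable scale.

Assumptions worth keeping in mind:

- **Locally stationary arrivals.** The estimator is unbiased up to a known
  finite-window factor only while rates are roughly constant across the
  window span; at change-points it mixes the two regimes until the window
  refills.
- **Window staleness.** If a pair stops co-occurring entirely, its last
  $N$ joint stamps freeze and the joint rate estimate stays at its old
  value indefinitely. Decay after an event is driven by *slow fresh
  co-occurrences diluting the window*, not by the passage of time itself.
  Interpret post-event series accordingly.
- **Finite-window bias.** On a homogeneous Poisson stream of rate
  $\lambda$, the span $\tau_N-\tau_1$ is Gamma$(N-1,\lambda)$, so
  $E[\hat\Phi] = \lambda\,(N-1)/(N-2)$ — about $+3.6\%$ at $N=30$. The
  test suite verifies this factor to 1% over $10^4$ windows. The bias
  largely cancels in the TSS ratio.

## Tunable parameters

- `n` (window size, messages; default **30**): the number of most recent
  matching messages per rate estimate. Larger `n` lowers variance
  (relative SD $\approx 1/\sqrt{n-3}$) but widens the effective time
  window and slows event response; 30 matches the regime the measure was
  designed for (small fixed-size query results).
- `alpha` (scaling exponent, dimensionless; default **0.25**): applied to
  the rate ratio. TSS is monotone decreasing in `alpha` for ratios in
  $(0,1)$; self-similarity is 1 regardless — that invariance is why the
  exponent is read as applying to the whole ratio.
- Timestamps are real-valued **seconds**; all rates are per second. All
  queries are closed on the right (stamps $\le t$, never look-ahead).

## Conventions for degenerate inputs

- **Undefined rates.** Fewer than two stamps, or a zero span (all stamps
  equal), make a rate *undefined* — a value, not an error. Any similarity
  that needs an undefined rate is 0, which also covers terms absent from
  the corpus. This avoids infinities from duplicate timestamps.
- **Ratio clipping.** With finite windows the estimated joint rate can
  exceed an individual rate (the windows cover different spans); the ratio
  is clipped at 1 so TSS stays in $[0,1]$.
- **Matrix diagonal.** 1 for terms with a defined rate at that time, 0
  otherwise.
- **Term matching.** Case-insensitive token matching; tokens are maximal
  letter/digit runs, a leading `#` is kept so hashtags are distinct from
  bare words; a multi-word term matches only as a contiguous, ordered
  token run. This is a deterministic, documented convention — no stemming,
  lemmatization or language detection.
- **Ties.** Equal timestamps are allowed (file order breaks ties when
  loading). In the top-3 group score, ties in similarity break by
  vocabulary order; real-valued similarities make ties measure-zero, but
  synthetic matrices do hit them, so the rule is fixed and tested.
- **MDS sign.** Classical (Torgerson) scaling is deterministic up to axis
  sign; each axis is flipped so its first non-negligible coordinate is
  positive, making repeated runs identical.

## The synthetic stream generator

`stream_model()` defines a marked Poisson process: messages arrive at rate
$\Lambda$; each message draws one topic $k$ with probability $w_k$ and then
includes each vocabulary word independently with the topic's inclusion
probability $p_k(\cdot)$. This gives closed-form oracles for any pair,
$$\Phi(w)=\Lambda\sum_k w_k\,p_k(w),\qquad
  \Phi(w_1\wedge w_2)=\Lambda\sum_k w_k\,p_k(w_1)\,p_k(w_2),$$
and hence an analytic TSS (`true_tss()`). A topic mixture was chosen over
pairwise copulas because it yields these closed forms for *every* pair at
once and naturally produces category clusters (fruit-like, animal-like,
colour-like groups) of the kind used in the evaluation harness.
`event_schedule()` concatenates piecewise-constant segments
$[t_0,t_1)$ to emulate scheduled events (a draw, a crisis): a change-point
is just a boundary where weights or inclusion probabilities change.

What the generator deliberately does **not** emulate: burstiness and
self-excitation (retweet cascades), diurnal cycles, message length and
realistic text, spelling variation, or correlated inclusion beyond the
topic structure. Passing recovery tests therefore shows the estimators are
correct *under the model's assumptions*; on real streams, bursty arrivals
inflate rate variance and the windowed estimates will be noisier than the
Poisson calibration suggests.

Within-message word order is the fixed vocabulary order; matching is
order-insensitive, so this is immaterial.

## Dynamics analyses

- **Group-organisation score.** For each item, take its three most similar
  other items; score $h/3$ where $h$ is how many are groupmates
  (groups of four). For an i.i.d. random matrix the top-3 is a uniform
  3-subset of the $m-1$ others, so the expected mean score is $3/(m-1)$ —
  $3/31 \approx 0.0968$ for 32 items — which the suite verifies by Monte
  Carlo over $10^4$ matrices. Each item's group must have at least four
  members so a perfect score is attainable.
- **Anchor drift.** The mean similarity of a tracked concept to two fixed,
  disjoint anchor groups per time point. The optional 2-D trajectory
  embeds the anchors once, by classical MDS of the time-averaged
  $1-\mathrm{TSS}$ dissimilarity, and places the concept at each time by
  Nelder–Mead least squares between its embedded distances and its
  current dissimilarities to the anchors. The projection is a convention
  of this package, chosen to be reproducible and anchored in a single
  frame so the trajectory is comparable across times.
- **Reorganisation norm.** The Frobenius norm of each matrix with the
  diagonal excluded. Frobenius is the standard choice for symmetric
  matrices and weighs all pairs equally; the diagonal is excluded because
  self-similarity is constant and carries no reorganisation signal.
  Subnetwork co-movement is quantified by the Pearson correlation of two
  norm series on a shared grid, optionally windowed.

## Classification harness

Items are split into $k$ seeded folds, stratified by class when every
class has at least $k$ members (plain random folds otherwise). Feature
columns are the *training* items: each item — train or test — is
represented by its similarity row over those columns, so a held-out item's
own similarity column is never among its features and its prediction rests
solely on its similarities to training items. Training rows keep their
stored self-similarity; an earlier variant that masked it to zero
conflated "self" with "maximally dissimilar" and collapsed small problems
where within-class similarity is high.

The shipped classifiers are k-nearest-neighbours (`class::knn`, default
$k_{nn}=1$) and Gaussian Naive Bayes (`e1071::naiveBayes`). They stand in
for the instance-based entropic-distance classifier used in the analyses
this package descends from; that classifier's internals are not publicly
specified, and the claims being tested (above-chance recovery of category
structure) are robust to the choice of standard classifier. For chance
calibration the suite assigns i.i.d. uniform labels, under which any
predictor independent of the held-out label is correct with probability
exactly $1/3$ for three classes.

## Problem sizes used by the test suite

The acceptance-style tests run at sizes chosen to give comfortable
statistical margins on a single CPU: estimator calibration at
$\lambda \in \{0.05, 0.5, 5\}$/s with $10^4$ disjoint 30-stamp windows per
rate; TSS recovery over 200 reference times per true ratio in
$\{0.1, 0.3, 0.6, 1\}$; the $3/31$ chance level over $10^4$ random
$32\times32$ matrices; event-response experiments (a 300 s group-aligned
"draw" segment among 16 items in 4 groups, and a concept-drift "crisis"
schedule) averaged over 50 replicate streams of 2400 s at 3–4 messages/s.
The simulator defaults in the test fixtures state the study conditions;
they are fixed, not tuned.

## Known limitations

- The estimator has no explicit forgetting: a pair that stops co-occurring
  keeps its last window's rate until fresh co-occurrences arrive (see
  staleness above).
- Conjunction queries are binary (pairs); higher-order co-occurrence is
  out of scope.
- Matching is surface-level and token-based; accent folding, stemming and
  language identification are deliberately not performed, so
  cross-language comparisons require the caller to supply per-language
  term lists.
- Matrices are recomputed independently per time point; no incremental
  update or approximate neighbour search is attempted.
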