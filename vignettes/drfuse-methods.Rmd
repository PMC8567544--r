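---
title: "Methods: multimodal similarity fusion and bilinear matrix completion for drug repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal similarity fusion and bilinear matrix completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Drug repositioning asks which approved drugs might treat diseases they are
not yet indicated for. The data are a sparse binary association matrix
$O \in \{0,1\}^{N_d \times N_g}$ (diseases in rows, drugs in columns,
$O_{ij} = 1$ for a known indication) together with side information: chemical
substructure fingerprints for drugs and a precomputed disease–disease
semantic similarity. The goal is to rank the unobserved cells of $O$ so that
true-but-unrecorded associations surface at the top.

`drfuse` implements a three-stage pipeline: per-entity similarity networks,
low-rank multimodal fusion of those networks into one feature vector per
entity, and inductive matrix completion over the fused features.

## Similarity networks

**GIP kernel.** The interaction profile of a disease is its row of $O$; of a
drug, its column. The Gaussian interaction profile kernel similarity between
entities $x, y$ with profiles $Y(x), Y(y)$ is

$$ s(x,y) = \exp\left(-\gamma \lVert Y(x) - Y(y)\rVert^2\right), \qquad
   \gamma = \frac{\gamma'}{\tfrac1n \sum_x \lVert Y(x)\rVert^2}, $$

the standard normalization by the mean squared profile norm, with
$\gamma' = 1$ by default (dimensionless; larger values sharpen the kernel).
An entity with no observed partners has a zero profile; its similarities
remain defined because the bandwidth is global, and only an entirely empty
association matrix is rejected. Inside cross-validation the GIP kernels are
recomputed from the *masked* training matrix, because profiles derived from
the full matrix would carry the held-out labels into the features.

**Fingerprint Jaccard.** For binary fingerprints $P, Q$ the similarity is
$|P \cap Q| / |P \cup Q|$ over set bits (the Tanimoto coefficient). Since
$0/0$ is undefined, a drug with an all-zero fingerprint scores 1 against
itself and 0 against everything else; a warning reports how many drugs hit
this convention.

**Semantic similarity** is consumed as a precomputed matrix (values in
$[0,1]$, symmetric, unit diagonal within $10^{-8}$); the package validates
but never computes it.

## Low-rank multimodal fusion

Each entity is described by $M$ modality vectors (its rows in the $M$
similarity networks of its side; $M = 2$ here, the code supports
$M \ge 1$). A full multimodal bilinear layer would form the outer product
$\mathcal{Z} = z_1 \otimes \cdots \otimes z_M$ and contract it with an
order-$(M{+}1)$ weight tensor $\mathcal{W}$, which is exponentially large.
Instead $\mathcal{W}$ is factorized as a sum of $\Re$ modality-wise rank-1
terms, $\mathcal{W} = \sum_{i=1}^{\Re} \bigotimes_m w_m^{(i)}$, giving the
equivalent factored form

$$ f = \sum_{i=1}^{\Re} \bigodot_{m=1}^{M} \left(z_m^\top w_m^{(i)}\right) + b, $$

with $\odot$ the element-wise product, computed in fixed modality order in
double precision. `full_tensor_oracle()` materializes the tensor form
explicitly (capped at test scale) purely to validate `lmf_transform()`; their
agreement to $10^{-8}$ over randomized instances is the central correctness
property of the fusion stage and is asserted in the test suite.

A constant 1 is appended to every modality vector by default
(`append_one`), so unimodal and lower-order interaction terms survive the
product; without it the fused map is strictly multilinear and any zero
modality annihilates the output.

**Initialization.** `init_fusion_factors()` offers seeded Gaussian factors
(scale $1/\sqrt{\Re\, d_m}$) and a structured *passthrough* scheme that
`fit_joint()` uses by default: rank terms are assigned round-robin to
modalities, a term's non-owning factors contribute exactly 1 through the
appended constant, and the owning factor is a Gaussian projection. The fused
map therefore starts as an additive random projection of the concatenated
modalities — a well-conditioned linear starting point — and gradient
training moves it toward genuinely multiplicative cross-modality terms. We
adopted this after observing that fully random initialization leaves plain
gradient descent in a poorly scaled region where the backtracking step size
collapses and the fit, at equal budget, ranks markedly worse.

## Inductive matrix completion

With fused features $X \in \mathbb{R}^{N_d \times f_d}$ and
$Y \in \mathbb{R}^{N_g \times f_g}$, pair $(i,j)$ is scored by the bilinear
form $x_i P y_j^\top$ with $P = W H^\top$ constrained to rank $f_p$ — the
usual trace-norm-motivated surrogate of a low-rank constraint. The training
objective is

$$ \min_{W,H} \sum_{(i,j)} \left(O_{ij} - x_i W H^\top y_j^\top\right)^2
   + \frac{\lambda}{2}\left(\lVert W\rVert_F^2 + \lVert H\rVert_F^2\right), $$

summed over **all** pairs, unobserved cells treated as 0 — standard for
implicit-feedback completion and the reading consistent with an
unrestricted double sum. The regularizer uses a plus sign: the
difference-of-norms variant sometimes seen in print is non-coercive
(minimizable to $-\infty$) and cannot be what a trace-norm relaxation
means. An optional weight `pos_weight` $\ge 1$ on positive cells is exposed
(default 1; it did not help on the synthetic benchmark).

**ALS.** With $H$ fixed, the optimal $W$ solves the Stein equation
$(X^\top X)\, W\, (B^\top B) + \tfrac{\lambda}{2} W = X^\top O B$ with
$B = YH$, solved exactly via symmetric eigendecompositions (denominators
floored at $10^{-10}$ against singular systems); symmetrically for $H$.
Because each half step is an exact minimizer, the objective is
non-increasing — asserted over random instances in the tests. For
`pos_weight > 1` each half step minimizes a majorizing surrogate
(weighted residuals folded into a modified target), which preserves
monotonicity in the weighted objective. Note the factors themselves are not
identifiable — only $P = WH^\top$ is; scores are invariant under
$(WG, HG^{-\top})$.

**Joint training.** `fit_joint()` chains the stages: similarity
construction, passthrough fusion initialization, a short ALS warm start for
$W, H$ on the initial features, full-batch gradient descent over *all*
parameters (fusion factors, biases, $W$, $H$) with backtracking (a step
that fails to decrease the loss is rejected and the rate halved; accepted
steps grow it 10%), and a final ALS polish on the frozen fused features.
The loss trace is therefore non-increasing by construction, and the whole
fit is a deterministic function of the root seed, from which each stage
derives its own seed by a counter scheme.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `rank_disease`, `rank_drug` | 8 | fusion tensor rank $\Re$ per side |
| `out_dim_disease`, `out_dim_drug` | 128 | fused feature widths $f_d$, $f_g$ |
| `f_p` | 32 | rank of the bilinear projection $P$ |
| `lambda` | 20 | ridge penalty on $W, H$ |
| `gamma_prime` | 1 | GIP bandwidth pre-factor |
| `epochs` / `lr` | 50 / $10^{-4}$ | gradient refinement budget / initial rate |
| `pos_weight` | 1 | weight on observed positive cells |

Defaults were selected by the package's own protocol — a 10-fold
cross-validated sweep on the default synthetic benchmark (`grid_search()`
automates the rank dimension of such sweeps) — and are sized for networks of
one-to-few hundred entities per side. On substantially larger real networks
the effective fusion ranks reported in the drug-repositioning literature are
an order of magnitude larger (hundreds); rerun `grid_search()` rather than
trusting any fixed default. $\lambda$ matters most: it controls how much the
model memorizes the training network through the near-diagonal GIP channel
versus generalizing through the cross-entity channels.

## The synthetic benchmark

`generate_bundle()` draws latent factors $U$ (diseases) and $V$ (drugs)
i.i.d. standard normal with `latent_dim` 8, sets cell $(i,j)$ positive with
probability $\sigma(u_i \cdot v_j + c)$ — $c$ calibrated by bisection so the
expected density is 0.05 within 0.005 — then flips each cell independently
with probability `flip_noise` = 0.02. Fingerprint bit $b$ of drug $j$ is
Bernoulli$(\sigma(v_j \cdot \beta_b))$ with $\beta_b \sim N(0, I/8)$ (unit
logit variance); disease semantic similarity is the Gaussian kernel of $U$
at the median pairwise distance, perturbed by symmetric noise of sd 0.05,
clipped to $[0,1]$ with unit diagonal. The default 120 × 150 size keeps a
full 10-fold cross-validation to roughly twenty seconds on one CPU, which is
the problem size used throughout the tests and the acceptance script.

What it emulates: a genuinely low-rank bipartite signal whose side
information on both sides is correlated with the latent factors — the
regime the model assumes. What it does not emulate: the heavy-tailed degree
distributions, block structure, and curated-database biases of real
indication networks, and fingerprints whose bits are correlated by shared
substructures rather than independent given $V$. Passing recovery tests
here demonstrates internal consistency of the machinery, not real-data
performance.

Two intrinsic ceilings of this generator are worth recording, since the
package's evaluation protocol makes them measurable. Conditional on
$(U, V)$, held-out cells are independent Bernoullis whose success
probability is monotone in $u_i \cdot v_j$, so ranking by the true latent
signal is Bayes-optimal; no fitted scorer can beat it in expectation.
Computed directly, that ceiling is AUROC $\approx 0.83$ at the default
`flip_noise` (about 27% of realized positives are pure flip noise) and
$\approx 0.945$ for the noise-free generator at the default seed. The fitted
pipeline reaches mean 10-fold CV AUROC $\approx 0.76$ and $\approx 0.86$
respectively (the acceptance script recomputes these), with the remaining
gap attributable to finite data and the GIP channel's partial memorization
of the training network.

## Evaluation protocol

Positives are dealt round-robin into $k$ folds (default 10) after a seeded
shuffle. Per fold: held-out positives are zeroed in the training matrix,
GIP similarities are rebuilt from the masked matrix, the model is retrained
from scratch, and test cells — the fold's positives against every
never-observed pair — are scored. AUROC uses the midrank (Mann–Whitney)
form, ties counted ½; AUPRC is the step integral of precision over recall
with tied scores grouped. The accuracy/F threshold is chosen to maximize
F-measure on the fold's training cells and then applied unchanged to the
test cells, since a threshold tuned on test scores would leak. Per-fold
means are the primary aggregate; pooled metrics over all test predictions
are also reported since the two differ when folds are uneven.

The case-study protocol (`rank_drugs_for_disease()`) deletes the target
disease's entire association row, retrains, and reports the top-$k$ drugs,
ties broken by drug id for determinism. No post-hoc filtering of
implausible candidates is attempted.

## Numerical and degenerate-input conventions

* All values are doubles end to end; matrix text I/O prints 17 significant
  digits, so round trips are bit-exact for finite values.
* Element-wise products across modalities run in input order, keeping
  results bit-stable across runs.
* Squared distances in the GIP kernel are clamped at 0 before
  exponentiation to absorb cancellation; outputs are symmetrized.
* ALS denominators are floored at $10^{-10}$; the noiseless recovery tests
  run at $\lambda = 10^{-9}$ through this path.
* Degenerate inputs fail loudly: all-zero profile matrices (undefined
  bandwidth), non-binary associations, asymmetric semantic similarity,
  ragged or non-numeric matrix files (errors name the offending line or
  cell).

## Known limitations

* The fusion stage's gradient refinement contributes little beyond the
  ALS-polished passthrough features on the synthetic benchmark; its value
  on real data, where cross-modality interactions may matter more, is
  untested here.
* The negative class for evaluation is "all unknown pairs", the field's
  convention; true-but-unrecorded associations therefore count as errors,
  and reported AUROC understates real performance to an unknown degree.
* Grid search re-fits the full pipeline per grid point; on large networks
  pair it with `neg_sample` to keep metric computation proportionate.
* The semantic-similarity input is trusted after validation; no attempt is
  made to detect scale drift between its source and the association data.
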