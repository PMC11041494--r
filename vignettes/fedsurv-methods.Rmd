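---
title: "Federated survival SVMs: model, protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated survival SVMs: model, protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsurv)
```

## The estimator

`fedsurv` fits a linear survival SVM with the *regression* objective: with
features $x_i \in \mathbb{R}^p$, survival time $y_i > 0$ in days, and event
indicator $\delta_i \in \{0, 1\}$,

$$
\min_{w, b} \; \frac{1}{2}\lVert w \rVert^2
  + \frac{\alpha}{2} \sum_{i=1}^n \zeta_i^2, \qquad
\zeta_i =
\begin{cases}
  \log y_i - (w^\top x_i + b) & \delta_i = 1,\\[2pt]
  \max\!\bigl(0,\; \log y_i - (w^\top x_i + b)\bigr) & \delta_i = 0.
\end{cases}
$$

Times are natural-log-transformed once at dataset construction and the model
lives entirely on the log-time scale; predictions are log-times (anti-risk:
larger is better). The censored branch is a squared hinge: a censored time
is a lower bound on the unobserved event time, so the model is penalized
only for predicting *below* that bound. The intercept is never regularized.
The objective is convex (a sum of convex pieces), and piecewise quadratic in
$(b, w)$, so a truncated Newton method converges in a handful of rounds.

At the hinge kink ($\zeta_i = 0$ for a censored sample) the loss is
differentiable with value 0 but the Hessian jumps; we use the subgradient
choice 0, i.e. a sample enters the active set only while
$\delta_i = 1$ or $\zeta_i > 0$. The kink set has measure zero and the
choice matches the active-set convention of reference SVM solvers; the
finite-difference agreement checked in the test suite confirms it is
consistent.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | `1e-4` | loss weight $\alpha$ (unitless); the $\tfrac12\lVert w\rVert^2$ term is fixed, so *smaller* `alpha` = *stronger* shrinkage |
| `fit_intercept` | `TRUE` | unregularized baseline log-time $b$ |
| `max_iter` | `50` | cap on outer Newton rounds |
| `grad_tol` | `1e-5` | stop when $\lVert \nabla f \rVert_\infty$ of the *global* gradient falls below this |
| `cg_tol` | `1e-8` | relative residual at which the inner conjugate-gradient solve truncates |

`alpha = 1e-4` with an intercept and at most 50 rounds is the reference
hyperparameter set used for every central-vs-federated comparison in this
package. Note its statistical consequence: at $n = 1000$ the implied ridge
factor shrinks weights roughly by $1/(1 + 1/(\alpha n)) \approx 1/11$.
Discrimination (c-index) is unaffected — it is invariant to monotone
rescaling — but *parameter recovery* experiments must neutralize the
penalty, so the recovery suite runs at `alpha = 1`, where the ridge term is
negligible relative to the data term.

### Initialization and line search

Optimization starts at $w = 0$, $b = $ mean of the log-times (itself a
federated aggregate), a deterministic and scale-reasonable start. Each
Newton direction comes from conjugate gradient truncated at `cg_tol`, at
$p + 1$ iterations, or at nonpositive curvature; if the resulting direction
is not a descent direction the round falls back to steepest descent (and
logs it). Steps use Armijo backtracking with factor $1/2$ and
$c_1 = 10^{-4}$, stopping after 30 halvings (the fit is then flagged
`converged = FALSE`). Every line-search objective evaluation is a federated
aggregation of per-site loss parts, so the simulated protocol is honest
about communication: the per-round log records objective evaluations and
message counts.

## The federation protocol

Horizontal partitioning — same features, different samples per site — makes
the loss part of the objective, its gradient, and its Hessian *additive
across sites*. Clients therefore exchange, per round, the triple
$\bigl(\tfrac{\alpha}{2}\sum \zeta_i^2,\; \nabla_{(b,w)} \text{loss},\;
\nabla^2_{(b,w)} \text{loss}\bigr)$ of dimension $1 + (p{+}1) + (p{+}1)^2$;
the coordinator sums them, adds the regularizer exactly once, and never sees
any sample. With one client the code path *is* the centralized fit, which
makes equality between federated and central fitting testable bit for bit.

Design choices a maintainer should know:

* **Full Hessian exchange, not Hessian-vector products.** CG then runs
  entirely coordinator-side on the summed Hessian, costing one exchange per
  round instead of one per CG iteration. The $O(p^2)$ payload is acceptable
  at clinical-table scale ($p$ up to a few thousand); for much wider data a
  matrix-free variant would be the first thing to revisit.
* **The intercept travels with the parameter vector** (first coordinate),
  and the convergence check uses the aggregated global gradient — the same
  stopping rule as the centralized fit.
* **Transport is simulated in-process**: clients are closures exposing only
  `summary_at(theta)` / `objective_at(theta)`; the coordinator cannot reach
  their data fields (an API-audit test greps the coordinator sources for
  dataset field access). A real network backend could replace the message
  layer without touching the math; sockets, TLS, and platform packaging are
  deliberately out of scope.

## Secure aggregation

With `use_smpc = TRUE` every exchanged tensor is masked by additive secret
sharing. Each scalar is first encoded as a fixed-point integer
$v = \operatorname{round}(x \cdot s)$ with scale $s = 10^{10}$, living in
the ring $\mathbb{Z}_M$ with $M = 2^{256}$ (sixteen 16-bit limbs; all limb
arithmetic is exact). A client splits $v$ into $n$ shards — $n - 1$ uniform
ring elements plus the modular remainder — routes shard $k$ to client $k$,
each client sums what it received, and the coordinator sums the $n$ partial
sums and decodes. Any $n - 1$ shards are jointly uniform, so no proper
coalition of that size learns a value; the price is $n^2$ shard messages
per tensor.

Masking *floating-point* numbers directly would corrupt low-order bits
(catastrophic cancellation against huge masks); integer encoding makes
reconstruction exact up to one initial rounding of each input, i.e. an
elementwise error at most $n / s = n \cdot 10^{-10}$. Empirically the
end-to-end weight difference between masked and plain federation is below
$10^{-6}$ — orders of magnitude under the $10^{-3}$ envelope that matters
for model equality. The scale must also keep
$|x| \cdot s < 2^{53}$ so encoding stays exact in doubles; at $s = 10^{10}$
that bounds exchanged magnitudes by $\sim 9 \times 10^5$, ample for
normalized features (Hessian entries grow like $\alpha n$), and violations
raise an explicit overflow error rather than silently wrapping. Threat
model: honest-but-curious parties; no differential privacy, homomorphic
encryption, or malicious-adversary defenses are attempted.

## Preprocessing

*Normalization.* Clients reveal only $(n, \sum x, \sum x^2)$ per feature
(exchangeable through the secure sum); the coordinator forms global mean and
**population** (divide-by-$n$) standard deviation — the additive
decomposition is then exact, so federated statistics equal pooled statistics
to machine precision, for every partition. Constant features get
$\sigma \mapsto 1$ and a flag, mapping them to exact zeros. Statistics are
computed on training folds only and applied to test folds. z-scoring is this
package's choice as the standard companion to SVM objectives; min-max
scaling would be a drop-in alternative.

*One-hot encoding.* Clients exchange only the sets of category levels they
observe; the vocabulary is the union, sorted deterministically (numerically
when every level parses as a number, C-locale lexicographically otherwise).
Every level gets an indicator column — no reference level is dropped, since
the ridge penalty absorbs the collinearity and keeping all levels makes the
encoding independent of client order. Two-level columns collapse to a single
0/1 indicator. Unseen levels at prediction time produce all-zero indicator
rows plus a warning.

## Evaluation

`harrell_cindex` uses the classical pair rules: pair $(i, j)$ is comparable
when $t_i < t_j$ and $\delta_i = 1$, or when $t_i = t_j$ and exactly one of
the two had the event (the event member must then carry the higher risk);
both-event ties are not comparable. Tied risks count $1/2$. All-censored
input raises an explicit undefined-result error rather than returning 0.5.
**Risk orientation matters**: the evaluator consumes risks where higher
means earlier expected event, so pass `predict(fit, d, type = "risk")`
(negated log-time); a silent sign error reports $1 - c$.

The *federated* c-index is the unweighted mean of per-site values — a
deliberate, documented difference from the pooled c-index, since sites never
exchange per-sample risks (a sample-weighted variant sits behind
`weights = "samples"`). In cross-validation we average site means within a
fold and then across folds, and also report the pooled-per-fold average, so
both aggregation orders are visible in the CV report.

Linear SHAP is closed-form, $\phi_{ij} = w_j (x_{ij} - \mu_j)$ with base
value $w^\top \mu + b$, satisfying local accuracy exactly; $\mu$ should be
the (federated) training mean, which is $\approx 0$ after z-scoring.

## The synthetic generator

`generate_survival` draws standard-normal features and log-normal event
times $\log T = w^\top x + b + \varepsilon$, $\varepsilon \sim
N(0, \texttt{noise\_sd})$ — the generative family under which the squared
$\zeta$ loss is well-specified, making parameter recovery a sharp test.
Censoring times are independent draws with matching spread whose location is
set by an empirical quantile of $\log T - \text{draw}$, so the realized
censored fraction hits the target up to discreteness (binomially close for
independent replicates). Defaults are the package's canonical study
conditions: $n = 500$, $p = 10$, weights $N(0, 1)/\sqrt{p}$ (unit total
signal variance at any $p$), intercept 5 log-days ($\approx 150$ days
median), `noise_sd = 0.3` (moderate individual noise, yielding c-indices in
the high-0.8s), 30% censoring. Client splits follow largest-remainder
rounding (100%, 20/50/30, or 5×20% in the shipped scenarios), and the batch
effect adds one $N(0, \sigma_{\text{batch}})$ offset vector per site — an
additive location shift, the simplest site-effect mechanism.

What the generator does *not* emulate: correlated or heavy-tailed features,
nonlinear or interaction signals, informative (outcome-dependent) censoring,
covariate-dependent censoring, or the empirical distributions of real
clinical cohorts. Passing tests therefore demonstrate *protocol
correctness* (federated = central, masking exactness, evaluator validity)
and estimator sanity under a well-specified model — not clinical
performance on any real dataset. The `preset_shape` sizes (150×1995,
15564×10) reproduce published data *shapes* for stress tests only.

## Problem sizes and numerical tolerances

The shipped test and acceptance experiments use $n \le 2000$, $p \le 20$
(plus one 150×1995 shape check) and 10-seed batteries — sizes chosen so the
whole suite runs in seconds on a laptop while every claim (equivalence at
$10^{-10}$, divergence below $10^{-3}$/$2\times10^{-4}$, SMPC drift below
$10^{-6}$, recovery within 0.1) is exercised at full fidelity; the
federated-central comparison is partition-invariant, so larger $n$ changes
nothing structurally. Duplication identities, convexity along random chords,
and finite-difference agreement (relative $10^{-5}$, step $10^{-6}$) guard
the calculus; the scikit-survival-equivalent oracle fit is frozen into the
suite at $10^{-4}$ agreement.

## Known limitations

* Only the regression objective (rank ratio 0) is implemented; the ranking
  objective and kernel survival SVMs are out of scope (federated ranking and
  federated kernel matrices are open problems in their own right).
* The federated c-index is a mean of site statistics, not the pooled
  c-index; with very small or very heterogeneous sites the two can differ
  noticeably, which the CV report makes visible.
* Security is limited to hiding individual contributions inside exact sums
  among honest-but-curious parties; aggregate leakage (e.g. through many
  rounds) is not quantified, and no poisoning defenses exist.
* The in-process transport models message *content and counts*, not
  latency, dropout, or asynchrony.
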