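---
title: "Topology tests, selection bias, and confidence sets of trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology tests, selection bias, and confidence sets of trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotest)
```

## The problem

A topology test asks whether a particular unrooted tree shape $\tau$ can be
rejected as the true evolutionary history of a set of aligned sequences.
Equivalently, running the test over a candidate set of topologies at level
$\alpha$ yields a $(1-\alpha)$ *confidence set of trees*: the candidates
whose P-value exceeds $\alpha$ (strictly — a tree with $p = \alpha$ is
excluded).

In practice the alternative hypothesis is almost never a fixed tree: it is
the maximum-likelihood (ML) tree $\hat\tau$, *selected by the same data*.
Because $l(\hat\tau) \ge l(\tau')$ for every fixed $\tau'$, plugging
$\hat\tau$ into a two-tree test inflates the test statistic relative to its
null distribution — the *selection bias* this package is built to study and
correct. Selection bias is most severe when many candidates compete for ML
status, i.e. when internal edges of the true tree are short or exactly
zero; with zero-length edges several topologies are simultaneously true
(3 with one zero edge, 9 with two separated, 15 with two adjacent zeros on
six taxa), and coverage is averaged over all of them.

## The tests

All tests consume a trees $\times$ sites matrix of per-site log-likelihoods
(`site_loglik`), either produced by the built-in engine
(`fit_topologies()`) or imported from external ML software
(`parse_sitelh()`).

**KH** (`kh_pvalues()`): a one-sided $z$-test on the site log-likelihood
differences $d_i = l_i(\hat\tau) - l_i(\tau)$, $H_0\!: E[d_i] = 0$ against
$E[d_i] > 0$, using $\widehat{\mathrm{Var}}(\bar d) = s_d^2/n$. The test
was designed for two *fixed* trees; the package follows the standard
$z$-test variance convention (the literal per-site reading
$\mathrm{Var} = s_d^2$ is available behind `per_site_variance = TRUE` for
sensitivity analysis — it makes the test wildly conservative and is not
the intended scale, as the agreement between the normal and RELL-bootstrap
variants confirms). For the ML tree itself the default P-value is 1 (no
evidence against the best tree); pairing it against the second-best tree,
as some software reports, is available via `ml_tree = "second_best"`.

**Chi-square** (`chisq_pvalues()`): $P[\chi^2_p > 2\{l(\hat\tau)-l(\tau)\}]$
with $p$ = the number of edges that must be contracted to reconcile the two
trees (half the Robinson–Foulds distance for binary trees). This bounds the
true null distribution, a mixture of $\chi^2$ variables, so the test is
conservative for fixed pairs. The known mixture weights at $p \le 2$ give
the *low-df refinement* (`low_df = TRUE`): $P[\chi^2_1 > y]/2$ at $p = 1$
and $P[\chi^2_1>y]/2 + P[\chi^2_2>y]/2$ at $p = 2$.

**SH** (`sh_pvalues()`): RELL bootstrap (resampling estimated
log-likelihoods — sites are resampled, parameters are not re-estimated)
shared across all candidates, each tree's bootstrap sums centered at its
own bootstrap mean — the least-favourable configuration in which every
candidate is equally good — and the P-value is the tail frequency of
$\max_j \tilde l_b(j) - \tilde l_b(\tau)$ against the observed
$l(\hat\tau)-l(\tau)$. Ties count toward the tail (the usual bootstrap
convention $P(T^* \ge t)$), so degenerate identical candidates get $p = 1$
rather than 0.

**AU** (`au_pvalues()`): the multiscale bootstrap. Bootstrap proportions
$\mathrm{BP}_r$ (share of replicates in which $\tau$ has the top resampled
log-likelihood; exact ties split evenly) are computed at resampling
fractions $r \in \{0.5, 0.6, \ldots, 1.4\}$, and
$\Phi^{-1}(1-\mathrm{BP}_r)$ is regressed on $(\sqrt r, 1/\sqrt r)$ by
weighted least squares with binomial-variance weights on the probit scale;
the fitted signed distance $d$ and curvature $c$ give
$p = 1 - \Phi(d - c)$. Scales with $\mathrm{BP}_r = 0$ carry no finite
probit and are excluded; $\mathrm{BP}_r = 1$ is clamped to $1 - 1/(2B)$.
Because $\Phi^{-1}$ explodes near the endpoints the procedure is unstable
exactly when support is very low, so by default the P-value is forced to 0
whenever the scale-1 BP is 0 (`bp0_correction`, the recommended reporting
rule; `AUu` in `topology_tests()` is the uncorrected variant kept for
comparison). The printed regressor pair is taken as
$(\sqrt r, 1/\sqrt r)$ — the standard multiscale-bootstrap geometry, in
which $d\sqrt{r} + c/\sqrt{r}$ matches the scaling of a boundary distance
and curvature under an $r$-fold change of information.

## Selection-bias corrections

For a tested tree $\tau$, the null is recast as the strict consensus
$\tau_0$ of $\tau$ and $\hat\tau$ (the projection of the ML tree onto the
null), and the effective alternative space is the compatible set
$A(\tau_0)$ — every candidate containing all splits of $\tau_0$, found by
the integer split-labelling scheme that `compatible_set()` implements.
Given any two-tree base test $p(\tau, \tau')$ (chi-square by default, KH or
a user closure via `base_test`):

* **Bonferroni** (`bonferroni_pvalues()`):
  $1-\{1-p\}^{|A(\tau_0)|}$, the independent-tests form, which unlike the
  raw product $|A|\,p$ is always a probability. `mode = "ml"` (cheap,
  default) uses $p(\tau,\hat\tau)$; `mode = "minimum"` the minimum over
  $A(\tau_0)$, which is less conservative because the ML pairing maximises
  the statistic but also the degrees of freedom.
* **Benjamini–Hochberg** (`bh_pvalues()`):
  $|A(\tau_0)|\min_k p_{(k)}/k$ over the ordered base P-values, capped at
  1; never larger than the raw-product Bonferroni.
* `minimum_pvalues()` exposes the *uncorrected* minimum — the quantity
  whose anti-conservatism the corrections repair, used to measure the
  selection-bias effect itself.

## Split supports and aLRT

Any confidence-set procedure induces a split support:
$1 - \max\{p(\tau) : \tau \not\ni s\}$ (`split_support_from_pvalues()`,
tabulated across methods by `split_supports()`). Conversely the aLRT
family works per split of the ML tree: with $l_1$ the ML log-likelihood
and $l_2$ the better of the two nearest-neighbor-interchange alternatives
across the focal split, the cubic aLRT support is $F^*(2\{l_1-l_2\})^3$,
$F^*(x) = 1/2 + P[\chi^2_1 \le x]/2$; the aLRTc variant
$1-(m-3)(1-\mathrm{aLRT})$ additionally corrects for testing all $m-3$
splits at once and is deliberately *uncapped* — negative values are
reported as such, a reminder that it is a corrected bound, not a
probability. Tree-level tests follow by duality: $M(\tau)$ is the largest
support among ML splits incompatible with $\tau$, giving $p = 1-M(\tau)$
(aLRT) and $(m-3)\{1-M(\tau)\}$ (aLRTc, capped at 1 only where set
membership requires a probability; the ML tree itself reports $m-3$).
`l2` comes from full edge-length re-optimization of each NNI alternative —
looked up from the fitted candidate set when it is exhaustive — rather
than a local-update shortcut; this is simpler to reason about and, if
anything, conservative.

## Likelihood engine and simulator

The engine is deliberately small: HKY85 with stationary frequencies
$\pi$, transition/transversion ratio $\kappa$, rate matrix scaled to one
expected substitution per site per unit edge length, and discrete-gamma
rate variation with equal-weight categories whose rates are within-bin
means (so the category rates average exactly 1). Likelihoods come from
Felsenstein pruning over compressed site patterns; with at most a couple
dozen taxa no per-node rescaling is needed (per-pattern likelihoods stay
far above double underflow), and conflicting states across an exactly
zero-length path yield $-\infty$ site log-likelihoods rather than an
error, so constrained consensus fits remain well defined.

Edge lengths are optimized by cyclic ascent: a preorder sweep maintains
exact outside/subtree partials so each edge reduces to a one-dimensional
problem in the eigenbasis of the rate matrix, solved by safeguarded Newton
steps bounded to $[0, 10]$ with the zero boundary attainable exactly.
Starting lengths are 0.1 and a cycle that improves the log-likelihood by
less than $10^{-6}$ stops the fit (at most 100 cycles). Substitution
parameters ($\kappa$, $\alpha$) are *frozen* — at their generating values
in simulations, or at import time for external matrices — never
re-estimated per topology: the study design does not prescribe
per-topology model refitting, and freezing keeps 105-candidate fits fast
and strictly comparable across topologies. The test suite verifies the
engine against phangorn's independent implementation, against the
Jukes–Cantor closed form, and against exhaustive pattern-probability sums.

`study_tree()` builds the simulation trees: caterpillar topologies on
$m$ taxa, terminal edges 0.1, internal edges set by the scenario
(`positive`, `one_zero`, `two_separated_zero` = internal edges 1 and 3
zeroed, `two_adjacent_zero` = edges 1 and 2, `star`). The published
figures fix only the *pattern* of zeros, not which labelled edges carry
them; since the simulation model is exchangeable over taxon labels, the
canonical placement used here leaves every coverage and set-size
distribution unchanged. `simulate_alignment()` draws i.i.d. sites —
gamma category, root state from $\pi$, HKY transitions down each edge —
and is byte-reproducible from its seed.

## The Monte Carlo harness

`run_study()` reproduces the coverage experiments: simulate, fit all
enumerated candidates ($(2m-5)!!$; 105 for six taxa — enumeration is
capped at eight taxa, beyond which a user-supplied candidate list is the
only sensible interface), compute the requested P-values, record the 95%
sets. Replicate $i$ reseeds at `seed + i`, so results are independent of
execution order and any replicate can be reproduced alone. Coverage with
multiple true trees is the average inclusion frequency over all of them,
and every run satisfies the identity
$\text{mean size} = N_I - N_I \cdot \overline{\text{power}} + N_C \cdot
\text{coverage}$ to machine precision (checked in the tests).

Default problem sizes follow the study design: 1000 sites, HKY
$\kappa = 2$, $\pi = (0.1, 0.2, 0.3, 0.4)$, $\Gamma_4(\alpha = 1)$,
$B = 10{,}000$ RELL replicates for SH and per AU scale. The package's own
acceptance checks run 200 replicates per scenario — enough that the
Monte Carlo standard error of every checked quantity is a small fraction
of its published rounding — while the printed tables used 1000; both are
reachable through `n_reps`. Eight-taxon studies (10,395 candidates per
replicate) are implemented but are an explicit long-running opt-in, not
part of any default run.

## Numerical and design notes

* Split encoding is a bitmask over the fixed taxon order with the first
  taxon's side complemented away, making split identity an integer
  comparison and compatibility four bitwise intersections.
* Enumeration is stepwise taxon addition in a fixed edge order, so
  "lowest index" tie-breaking (e.g. for the ML tree) is reproducible.
* RELL resampling draws multinomial pattern weights (a uniform site draw
  binned by pattern); all trees share the weights within a replicate, and
  SH/BP/AU reuse one draw per (B, scale) where their settings coincide.
* KH bootstrap, RELL, and simulation honour `set.seed()`; the bulk RELL
  draws use a fast auxiliary generator whose state is itself seeded from
  R's stream, preserving reproducibility without per-draw RNG overhead.
* `topology_tests()` is the one-call surface returning a tidy tibble
  (one row per candidate, one `p_*` column per method); `tidy()`,
  `glance()` and `autoplot()` methods cover fitted candidate sets and
  study results.

## Limitations

* The built-in engine is nucleotide HKY+Γ only — by design. Analyses
  under richer models (GTR+G, amino-acid matrices) enter through
  `.sitelh` import, which carries every test but not the engine-dependent
  conveniences (aLRT refits need the fitted candidates).
* No ambiguity codes, gaps, indels, partitions, or model selection.
* AU P-values inherit the instability the BP = 0 correction patches over:
  near-zero and near-one bootstrap proportions still enter the probit
  regression with little information, and different published
  implementations make different micro-choices (weighting, scale handling,
  model parameter re-estimation) that visibly move mean set sizes in the
  hardest, near-star scenarios. Comparisons against other software should
  expect agreement in the well-resolved regimes and implementation-level
  spread when almost every candidate is nearly tied.
* The simulator emulates the i.i.d.-sites generative model exactly; it
  does not emulate real-data features such as alignment error,
  compositional heterogeneity, or site-specific selection, so passing
  coverage checks here demonstrates correctness of the procedures under
  the model, not robustness to model violation.
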