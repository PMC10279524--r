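---
title: "Replicability analysis with the max-p statistic and composite-null FDR control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicability analysis with the max-p statistic and composite-null FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpfdr)
```

# The model

The input is a paired p-value sequence $(p_{1i}, p_{2i})$, $i = 1,
\dots, m$, one pair per feature (gene) shared by two independent
high-throughput studies. Each feature carries hidden per-study states
$\theta_{ji} \in \{0, 1\}$; the joint state $\tau_i = (\theta_{1i},
\theta_{2i})$ takes the four values $(0,0), (0,1), (1,0), (1,1)$ with
proportions $\xi_{00}, \xi_{01}, \xi_{10}, \xi_{11}$ summing to one. A
feature is replicable iff $\tau_i = (1,1)$; the null hypothesis of the
replicability analysis is the composite event that $\tau_i$ is any of
the other three states.

Two assumptions drive everything:

1. **Uniform nulls.** Within each study, p-values of null features are
   (super-)uniform on $[0,1]$. This is the same assumption BH and
   Storey-type estimation rest on.
2. **Conditional independence.** Given the joint state, the two
   p-values of a feature are independent (the studies are separate
   experiments).

The test statistic is the maximum p-value $q_i = \max(p_{1i},
p_{2i})$. Under $(0,0)$ its CDF is $t^2$; under the one-sided null
states it is at most $t$. Averaging over the null states,

$$G(t) = \frac{\xi_{00} t^2 + (\xi_{01} + \xi_{10})\, t}
             {\xi_{00} + \xi_{01} + \xi_{10}}, \qquad
  G(t) - t = \frac{\xi_{00}}{\xi_{00} + \xi_{01} + \xi_{10}}\, t(t-1)
  \le 0,$$

so $q_i$ is super-uniform under the composite null — BH applied
directly to the $q_i$ (the "MaxP" procedure) is valid but pays for the
gap between $G(t)$ and $t$ with a large power loss whenever the
double-null state dominates, which it does in genome-scale screens.

The procedure implemented here closes that gap by plugging the state
proportions into the FDR estimate at candidate threshold $t$:

$$\widehat{\mathrm{FDR}}{}^*(t)
  = \frac{m(\hat\xi_{00} t^2 + \hat\xi_{01} t + \hat\xi_{10} t)}
         {R(t) \vee 1}, \qquad R(t) = \#\{i : q_i \le t\}.$$

The data-adaptive threshold is $\hat t_m = \sup\{t :
\widehat{\mathrm{FDR}}{}^*(t) \le \alpha\}$, realised as the step-up
rule: order $q_{(1)} \le \dots \le q_{(m)}$, set $\hat k = \max\{i :
\widehat{\mathrm{FDR}}{}^*(q_{(i)}) \le \alpha\}$, reject all features
with $q_i \le q_{(\hat k)}$. Between consecutive order statistics
$R(t)$ is constant and the numerator is increasing in $t$, so the
supremum is always attained at an order statistic; the two forms are
equivalent, and the suite verifies this against a dense grid-search
oracle on a thousand random instances.

# Estimation of the proportions

The per-study null proportions use the Storey tail estimator
$\hat\pi_0^{(j)}(\lambda) = \#\{p_{ji} \ge \lambda\} / (m(1-\lambda))$,
and the double-null proportion its bivariate analogue
$\hat\xi_{00}(\lambda) = \#\{p_{1i} \ge \lambda,\, p_{2i} \ge \lambda\}
/ (m(1-\lambda)^2)$. The remaining components follow by differencing:
$\hat\xi_{01} = \hat\pi_0^{(1)} - \hat\xi_{00}$, $\hat\xi_{10} =
\hat\pi_0^{(2)} - \hat\xi_{00}$, $\hat\xi_{11}$ as the remainder.

**Tuning-parameter selection.** Each raw estimate is computed over the
grid $\lambda = 0.05, 0.10, \dots, 0.95$ and smoothed by a cubic
smoothing spline with 3 effective degrees of freedom
(`stats::smooth.spline`), evaluated at the largest grid value — the
canonical q-value smoother. This was a genuinely open design point: the
originating description delegates the smoothing specifics to
supplementary material, so we adopted the cited smoother's standard
defaults (grid, df = 3, evaluation at $\max\lambda$) and kept them
fixed. Users can bypass smoothing entirely with `fixed_lambda` or
`smoothing = FALSE` in `estimate_proportions()`.

**Clipping.** Raw tail estimates can leave $[0,1]$. We clip
$\hat\pi_0^{(j)}$ to $[0,1]$ first, then clip $\hat\xi_{00}$ into the
Fréchet–Hoeffding interval $[\max(0, \hat\pi_0^{(1)} + \hat\pi_0^{(2)}
- 1),\ \min(\hat\pi_0^{(1)}, \hat\pi_0^{(2)})]$. How (or whether) the
original procedure clips is unstated; this order guarantees that the
four components form a valid probability distribution, that
$\hat\xi_{01}, \hat\xi_{10} \ge 0$, and that the total estimated null
mass is at most 1 — which in turn guarantees
$\widehat{\mathrm{FDR}}{}^*(t) \le m t / R(t)$, so the rejection set
always *contains* the MaxP-BH rejection set at the same level (a
property the tests assert).

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | nominal FDR level of the step-up rule |
| `grid` | 0.05…0.95 by 0.05 | $\lambda$ grid for the Storey estimators |
| `fixed_lambda` | none | single $\lambda$, bypassing the smoother |
| `df` (Lancaster) | `c(2, 2)` | per-study chi-square degrees of freedom; equal weights reduce to Fisher |

Adjusted replicability values are not part of the original rule; they
are the running minimum from the largest $q$ downward of
$\widehat{\mathrm{FDR}}{}^*(q_{(i)})$, capped at 1 — the exact analogue
of BH adjusted p-values, added so that "rejected at $\alpha$" and
"adjusted value $\le \alpha$" coincide and results can be reported at
any level after the fact.

# The synthetic-data generator

`simulation_scenario()` / `gen_states()` / `gen_pvalues()` emulate the
standard two-study Gaussian benchmark: states drawn i.i.d. from the
four-group multinomial; summary statistics $X_{ji} \sim N(\mu_j
\theta_{ji}, \sigma_j^2)$; one-sided p-values $p_{ji} = 1 -
\Phi(X_{ji}/\sigma_j)$. The benchmark configuration used by the
acceptance suite is $m = 10{,}000$, $\xi_{11} = 0.05$, $\xi_{01} =
\xi_{10} = (1 - \xi_{00} - \xi_{11})/2$ with $\xi_{00} = 0.9$, $\mu_1 =
\mu_2 = 3$, $\sigma_j = 1$, $\alpha = 0.05$, 100 replications; the
harness default grid also spans $\xi_{00} \in \{0.80, 0.85, 0.90\}$,
$\sigma \in \{1, 2\}$ and the mean settings $(2.5, 3)$, $(2.5, 2.5)$,
$(3, 3)$ — the axis values of the benchmark figure are not printed in
the source description, so these are configurable defaults chosen to
span weak-to-moderate signal at genome scale, not ground truth.

What the generator does **not** emulate: dependence between features
(spatial or co-expression correlation in real transcriptomics data),
non-Gaussian or heavy-tailed statistics, discretely supported p-values,
and more than two studies. A green simulation test therefore
establishes calibration under independence and Gaussian alternatives
only; on strongly dependent real data the FDR estimate inherits the
usual Storey-estimator caveats.

**Seeding.** One master seed per scenario; replication $r$ reseeds with
a deterministic child seed $(48271\,\mathrm{seed} + 16807\,r) \bmod
(2^{31}-1)$, so replications are individually reproducible and
independent of execution order. All randomness flows through these
seeds.

# Numerical choices and degenerate inputs

- p-values exactly 0 or 1 are accepted unmodified; no clamping.
- Ties in $q$: all features tied at $q_{(\hat k)}$ are rejected,
  consistent with the threshold form $q_i \le \hat t_m$.
- No order statistic qualifying: $\hat t_m = 0$, zero rejections;
  adjusted values are still computed.
- Empty replicability null ($\xi_{00} + \xi_{01} + \xi_{10} = 0$) makes
  $G$ undefined and raises an explicit error.
- $R(t) \vee 1$ prevents division by zero throughout.
- Fewer than 4 grid points cannot support the spline; the raw estimate
  at $\max\lambda$ is used with a warning.
- Proportions are renormalised after clipping to absorb floating-point
  drift before validation at tolerance $10^{-9}$.

# Known limitations

- Validity of the plug-in FDR estimate relies on uniform (not merely
  super-uniform) nulls for the $t^2$ term and on between-study
  independence; conservative one-sided nulls make the procedure more
  conservative, not invalid.
- Storey estimators are noisy near $\lambda \to 1$; the spline tames
  but does not remove boundary variance, and on small $m$ (a few
  hundred features) `fixed_lambda = 0.5` is often the more stable
  choice.
- A feature appended with $q = 1$ can only shrink the rejection set:
  the estimate scales with $m$ while $R(t)$ is unchanged, so marginal
  discoveries near the threshold may be lost — the same behaviour BH
  exhibits.
- Comparators with their own publications (adjusted partial-conjunction
  p-values, rank-based reproducibility, the irreproducible discovery
  rate) are not reimplemented; register external implementations in the
  method list passed to `run_scenario()`.

# A small demonstration

```{r demo}
sc  <- simulation_scenario(2000, four_group_proportions(0.9, 0.025, 0.025, 0.05),
                           mu1 = 3, mu2 = 3, seed = 5)
sim <- gen_pvalues(gen_states(sc, 1), sc)
est <- estimate_proportions(sim$pairs)
res <- jump_test(sim$pairs, est$joint, alpha = 0.05)
res
maxp_bh(sim$pairs, 0.05)
```
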