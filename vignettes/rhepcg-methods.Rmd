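---
title: "Methods behind rhepcg: randomized HE regression and matrix-free SNP-BLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind rhepcg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhepcg)
```

## The model

Everything in this package works with the additive genetic model

$$ y = X\theta + Zu + e, $$

where $y$ is the $n \times 1$ vector of (standardized) phenotypes, $X$ the
$n \times 1$ intercept incidence, $Z$ the $n \times m$ matrix of
standardized genotypes, $u$ the $m \times 1$ vector of marker effects with
$u_j \sim N(0, \sigma_g^2/m)$ on the scale used here, and
$e \sim N(0, \sigma_e^2 I)$. The genomic relationship matrix is
$\omega = ZZ'/m$; heritability is
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$.

Two deliberate conventions shape all the algebra:

* **Divisor-$n$ genotype scaling.** Each genotype column is centered and
  divided by its root-mean-squared deviation with divisor $n$ (not
  $n-1$), so every column of $Z$ has sum of squares exactly $n$ and
  $\mathrm{tr}(\omega) = n$ holds as an identity rather than an
  approximation. The unit tests assert it at $10^{-8}$.
* **The $Z^* = Z/\sqrt m$ marker block.** The mixed-model equations are
  assembled with $Z^* = Z/\sqrt m$ and ridge
  $\lambda = \sigma_e^2/\sigma_g^2$. The variance components estimated by
  both estimators in this package live on the GRM scale
  ($\mathrm{Var}(g) = \sigma_g^2\,\omega$), and under this scaling
  SNP-BLUP is algebraically identical to GBLUP with $G = ZZ'/m$ and ratio
  $\sigma_e^2/\sigma_g^2$. The alternative reading — unnormalized $Z$ with
  the same ratio — would apply $m$ times more shrinkage and silently break
  the equivalence with the GBLUP baseline, so the equivalence is pinned by
  a test (SNP-BLUP and GBLUP candidate predictions agree to $10^{-6}$)
  rather than assumed.

Candidate individuals are always standardized with the *training* column
means and scales: marker effects are estimated on the training scale and
only make sense applied on that scale. Phenotypes are standardized to mean
0, unit variance (divisor $n-1$) by default, with the raw mean/SD retained
so predictions can be mapped back.

## Heritability by randomized Haseman–Elston regression

Regressing phenotype products on genomic relatedness and contracting the
moment conditions $E[yy'] = \sigma_g^2\,\omega + \sigma_e^2 I$ with
$\omega$ and $I$ gives the $2 \times 2$ system

$$
\begin{pmatrix} \mathrm{tr}(\omega^2) & \mathrm{tr}(\omega) \\
\mathrm{tr}(\omega) & n \end{pmatrix}
\begin{pmatrix} \hat\sigma_g^2 \\ \hat\sigma_e^2 \end{pmatrix} =
\begin{pmatrix} y'\omega y \\ y'y \end{pmatrix}.
$$

Three of the four moments are cheap and exact: $\mathrm{tr}(\omega) = n$,
$y'y$, and $y'\omega y = \lVert Z'y\rVert^2/m$ (one $O(nm)$ pass — it is
not worth randomizing). Only $\mathrm{tr}(\omega^2)$ would need the dense
GRM, so it is estimated by the Hutchinson estimator with $S$
standard-normal probes $w_s$:

$$ \widehat{\mathrm{tr}(\omega^2)} =
   \frac{1}{S\,m^2} \sum_{s=1}^S \lVert ZZ'w_s \rVert^2, $$

each probe costing two matrix–vector products with $Z$. $S$ defaults to 5,
the working value of the full fit; the estimator is unbiased for any $S$
(tested against the dense trace) with per-probe variance
$2\,\mathrm{tr}(\omega^4)$, and the test suite uses exactly that Gaussian
variance bound when checking small-$S$ behavior. One consequence worth
knowing: the trace estimate enters the *denominator* of
$\hat\sigma_g^2 = (y'\omega y - y'y)/(\widehat{\mathrm{tr}(\omega^2)}-n)$,
so at small $S$ the heritability estimate carries a slight convexity
(Jensen) inflation on top of its Monte-Carlo noise. At the package's
default study sizes this is on the order of a few percent relative; users
who want it gone can raise `S` — cost is linear in `S`.

Method-of-moments estimates can leave the parameter space, and the
operative estimator is silent about that, so the package clamps:
$\hat\sigma_g^2$ to $[0, \hat\sigma_y^2]$ and $\hat\sigma_e^2$ to be
non-negative. A phenotype orthogonal to every marker therefore yields
$h^2 = 0$ exactly. Before the MME are formed, $h^2$ is further clamped
into $[0.001, 0.999]$ (with a warning) so $\lambda$ stays finite and
nonzero; a fit at the clamp boundary should be treated as uninformative.

The HE regression intercept that appears when one writes the estimator as
a pairwise regression of $y_i y_j$ on $\omega_{ij}$ never enters the
two-moment system above; the system is the operative estimator. A
brute-force off-diagonal pairwise regression is kept in the test suite as
an oracle — at $n = 30$ the two routes differ by under 25% relative,
a systematic $O(1/n)$ diagonal-term difference, and the moment system is
what the package reports.

## Solving the mixed-model equations matrix-free

The coefficient matrix

$$ A = \begin{pmatrix} X'X & X'Z^* \\ Z^{*\prime}X & Z^{*\prime}Z^* +
\lambda I \end{pmatrix} $$

is symmetric positive definite and is only ever touched through products
$Av$, computed via the shared intermediate $t = Xv_0 + Z^*v_1$ in $O(nm)$
work and $O(n+m)$ memory. The solver is textbook preconditioned conjugate
gradient with the Jacobi preconditioner $M = \mathrm{diag}(A)$, whose
entries are known analytically under divisor-$n$ scaling
($\mathrm{diag}(X'X) = n$, $\mathrm{diag}(Z^{*\prime}Z^*)_j = n/m$): no
dense pass is needed even for the preconditioner. Published listings of
PCG for this problem vary in notation and are not always internally
consistent; this package deliberately treats *solution correctness* as the
contract — the solver must match a dense direct solve of the same system
to $10^{-8}$ on randomized instances — rather than mimicking any
particular listing line by line.

Numerical choices:

* convergence when $\lVert b - Ax\rVert/\lVert b\rVert \le$ `tol`
  (default $10^{-8}$), measured on the recurred residual but re-verified
  on a freshly computed true residual before convergence is declared, and
  refreshed every 50 iterations to guard against drift;
* `max_iter` defaults to $10(m+1)$; in exact arithmetic CG terminates in
  at most $\mathrm{rank}(A)$ steps, and the tests assert $\le m+1$
  iterations on well-conditioned instances;
* start vector $x_0 = 0$; an arbitrary start (e.g. all-ones) converges to
  the same solution and a test asserts so;
* a detected $p'Ap \le 0$ aborts with the iteration number — with
  $\lambda > 0$ it can only arise from a malformed operator.

## The GBLUP/REML baseline

The baseline exists for two reasons: it is the conventional method the
fast path is compared against, and it is the *oracle* that pins the fast
path's correctness. It is intentionally the transparent $O(n^3)$ version:
$G = ZZ'/m$ with a cached eigendecomposition, restricted likelihood of
$y \sim N(1\theta,\ \sigma_p^2(h^2 G + (1-h^2)I))$ profiled over $\theta$
and $\sigma_p^2$ in the eigenbasis, and Brent search over
$h^2 \in [10^{-4}, 1-10^{-4}]$ (tolerance $10^{-8}$). A flat likelihood
(e.g. $G = I$) or an optimum at the clamp bound sets a `boundary` flag. A
generic dense two-parameter REML optimizer agrees with the profile to
$10^{-4}$ in the tests. BLUP uses
$\alpha = (G + \lambda_G I)^{-1}(y - 1\hat\theta)$ with the GLS intercept,
training values $G\alpha$ and candidate values through the
train–candidate block $(Z_{cand}Z_{train}'/m)\,\alpha$ — the same
quantities the PCG path produces through $\hat u$, which is exactly the
equivalence the oracle test checks.

## What the F2 simulator emulates

The generator mimics a classic two-inbred-line cross: one long chromosome
(default 2,000 markers, i.e. 1,999 intervals) with recombination fraction
$c = 0.01$ per interval — the marker count is not dictated by the
chromosome length alone, and 2,000 equally spaced markers (~1 cM apart,
where 1 cM ≈ $c$ = 0.01 at small distances) is the natural reading;
it is a config field, not a constant. Each gamete is a first-order Markov
chain along the chromosome (constant switch probability, no interference,
no map-function conversion); an F2 dosage is the sum of two independent
gametes, giving allele frequency 1/2 and genotype frequencies 1/4:1/2:1/4,
and adjacent-marker dosage correlation $1 - 2c$ — all of which the test
suite checks empirically at large $n$.

Every marker is a QTL with an i.i.d. $N(0,1)$ effect. Genetic values are
computed from the centered/scaled *cohort* design, not raw dosages, so the
simulated additive variance lives on the same GRM scale the estimators
report and "estimated $\hat h^2$ versus target $h^2$" is a like-for-like
comparison. The residual variance is calibrated to the *realized* genetic
variance of each replicate, $\sigma_e^2 = \mathrm{Var}(g)(1-h^2)/h^2$, so
realized heritability matches the target per replicate rather than only in
expectation — with ~2,000 markers in strong mutual linkage disequilibrium,
$\mathrm{Var}(g)$ for a single effect draw scatters by ~20% around its
expectation, and without the calibration that scatter would masquerade as
estimator bias.

Draw order per replicate is fixed (gametes, effects, residuals) under one
seed; replicate $r$ of an experiment uses `seed + r` and its HE probes
`seed + 100000 + r`, so toggling one method never perturbs another's
draws and identical configurations are bit-identical.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: multiple chromosomes, minor-allele-frequency
spectra other than 1/2, dominance/epistasis, genotyping error or
missingness, selection (which is known to drive method-of-moments and
likelihood heritability estimates apart), and population structure beyond
an idealized F2. Real-data use goes through the file loaders and the same
fitting functions, but the acceptance evidence here is simulation-only.

## Evaluation conventions

Predictive accuracy is the squared Pearson correlation between candidate
*phenotypes* and predicted genotypic values — deliberately the noisier
target, matching the field's reporting convention; the correlation against
true genetic values is carried as a supplementary column
(`r2_genetic`). Standard errors are sample SD (divisor reps − 1) over
$\sqrt{\text{reps}}$; with one replicate they are reported as `NA`.
Because realized heritability is calibrated per replicate, mean accuracy
should approach but not exceed $h^2$ as training size grows; a test
asserts the bound up to twice the Monte-Carlo standard error.

## Problem sizes and known limitations

The shipped test suite and the acceptance script run the replicated
scenarios at training sizes 300–2,000 with a 2,000-marker chromosome,
10–20 replicates per scenario — sizes chosen so the whole suite completes
in minutes on a single core while keeping the Monte-Carlo standard error
of scenario means near the 0.01–0.02 the original tables report. Property
tests that need an explicit dense oracle (dense MME solve, dense traces,
pairwise HE regression) run at $n \le 100$ where the dense route is exact
and instant.

Known limitations, stated plainly:

* With $S = 5$ probes the RHE heritability estimate at these scales has a
  per-scenario-mean scatter of roughly $\pm 0.03$ across seed blocks plus
  the small Jensen inflation discussed above; scenario means should be
  read with their standard errors, not as point reproductions.
* A correctly specified profile REML on this simulator is near-unbiased.
  Implementations differing in scaling conventions or likelihood
  parameterization can show materially biased heritability at the same
  sizes, so cross-implementation comparisons of $\hat h^2$ should fix
  conventions first (the GRM scale here is $\mathrm{tr}(\omega) = n$).
* Single fixed effect only (the intercept): covariate matrices,
  gene–environment interaction and multi-trait extensions are out of
  scope, as are APY-style sparse-inverse approximations and wall-clock
  benchmarking claims, which are hardware-bound (the benchmark subcommand
  prints elapsed time for information only).
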