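---
title: "Causal composition of small discrete dynamical systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal composition of small discrete dynamical systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalcomp)
```

## The model

`causalcomp` analyses distributed dynamical systems of $n$ binary elements
that update synchronously in discrete time, each according to its own
mechanism — a conditional probability $p(v_{i,t} = 1 \mid v_{t-1})$ over the
full prior system state. Boolean networks, logic-gate circuits and
elementary cellular automata on small lattices are all of this type. Two
assumptions are built in: the system is stationary (mechanisms do not change
over time), and there is no instantaneous causation, so the joint transition
probability factorises over nodes,

$$p(v_t \mid v_{t-1}) \;=\; \prod_i p(v_{i,t} \mid v_{t-1}).$$

A system is represented as a `tpm` object carrying both the
$2^n \times 2^n$ state-by-state matrix and the compact $2^n \times n$
state-by-node table of per-node on-probabilities. The two dialects are
interconvertible exactly when the factorisation above holds; deterministic
matrices always factorise, while generic probabilistic state-by-state
matrices need not. By default the package refuses to treat a
non-factorising matrix as a mechanistic system (`strict = TRUE`), because
every mechanism-level quantity below is defined through the per-node
conditionals; a lenient mode keeps such matrices for purely holistic
measures (entropy, effective information).

States are enumerated little-endian: the first node varies fastest, and a
printed string such as `"011"` assigns 0 to the first node. This single
convention is used for rows, columns, repertoires and file formats.

## From holistic baselines to state-dependent causal information

Predictive information $I(V_{t-1}; V_t)$ measures how well the next state
can be predicted from the previous one under a given prior over states.
Imposing the uniform (maximum-entropy) prior — equivalent to perturbing the
system into every state — yields the effective information $EI(S)$, the
average Kullback–Leibler divergence of each transition row from the mixture
of all rows. Both are *holistic*: they characterise the system as one
block, from the outside.

The package's core instead asks what each *subset* of elements, in its
current state, specifies about the prior and next states of other subsets
— information that exists for the system itself only if some mechanism
makes it explicit. For a mechanism $X$ in state $x_t$ and a purview $Z$:

* the **effect repertoire** $\pi(Z_{t+1} \mid x_t)$ is the product over
  purview nodes of the node's on-probability conditioned on $x_t$, with all
  other inputs fed independent maximum-entropy noise (causal
  marginalization). The factorisation discounts correlations that would be
  induced merely by common inputs.
* the **cause repertoire** $\pi(Z_{t-1} \mid x_t)$ inverts each mechanism
  *element's* conditional by Bayes' rule under a uniform perturbation prior,
  marginalizes onto $Z$, multiplies across elements and renormalizes. The
  uniform prior is not configurable: the quantity is meant to reflect the
  system's mechanisms and nothing else, so no observational prior may leak
  in.

Repertoires are interventionist objects, $\pi \ne p$ in general: the same
conditioning computed naively from the joint matrix
(`condition_and_marginalize()`) gives a different, correlation-contaminated
answer, which the test suite exhibits on probabilistic systems.

When a mechanism state cannot be produced by any prior state its cause
repertoire has a zero normalizer. The repertoire is then flagged undefined
and the mechanism's irreducible cause information is set to 0 with a
warning — the convention for systems that can in principle be perturbed
anywhere but deterministically never visit some configurations.

## Irreducibility: the minimum information partition

A mechanism only contributes information *as a whole* to the extent that no
partition of it reproduces its repertoire. A permissible partition splits
the mechanism into $m \ge 2$ non-empty parts and assigns each purview node
to exactly one part or to a leftover set that becomes unconstrained;
purview parts may be empty. The partitioned repertoire is the product of
the part repertoires times the unconstrained repertoire of the leftover.
The irreducible information $\varphi^C/\varphi^E$ is the Kullback–Leibler
divergence from the intact repertoire to the closest partitioned one (the
minimum information partition, MIP). Single-node mechanisms cannot be
partitioned; their $\varphi$ is the divergence from the unconstrained
repertoire.

Two design choices deserve comment:

* **Purview fixed to the full node set.** Because the divergence is
  additive over purview nodes that the mechanism does not constrain, the
  full purview attains the maximal $\varphi$, so no purview search is
  needed. The *effective purview* — the nodes whose constrained marginal
  differs from the unconstrained one — is reported for display and used for
  concept identity at the system level.
* **Empty mechanism parts are excluded.** Allowing a part $(Z \mid
  \varnothing)$ would let a single-node mechanism be "partitioned" against
  the empty set, collapsing its $\varphi$ to the least constrained purview
  node; that contradicts the single-node rule above and the reference
  values the package reproduces. Empty *purview* parts, by contrast, are
  essential: the full-system mechanism of the worked example is reducible
  precisely via a partition that pairs one mechanism part with the whole
  purview and the other with nothing.

Ties between co-minimal partitions are broken by the deterministic
enumeration order (set partitions in restricted-growth order, purview
assignments lexicographic); `all_mips = TRUE` retrieves every co-minimal
partition. $\varphi$ comparisons use an absolute tolerance of $10^{-9}$,
and $0 \log 0 := 0$ throughout.

`composition()` evaluates all $2^n - 1$ subsets in both directions and sums
them; $\sum\varphi^C + \sum\varphi^E$ is the total compositional intrinsic
information of the state.

## System-level integration

A set of elements forms one system, rather than several, only if every part
irreducibly constrains the rest. `big_phi()` evaluates the $2^n - 2$
unidirectional cuts $X \nrightarrow S \setminus X$: every node outside the
source has its inputs from the source replaced by independent noise
(averaging its on-probability over the source states), which preserves
row-stochasticity and conditional independence. A single cut TPM serves
both repertoire directions — the cut defines one modified network within
which causes and effects are re-evaluated, with the mechanism-level MIP
search re-run from scratch.

For each subset with positive intact $\varphi$ the loss under the cut is
accounted by the **concept rule** (the default): a mechanism's constraint is
identified by its effective purview, and if the cut changes that purview
the intact constraint no longer exists — its full $\varphi$ counts as lost —
while an unchanged purview contributes the difference
$\varphi - \varphi^\Psi$. The per-subset losses are summed separately over
the cause and effect sides, and

$$\Phi \;=\; \min_\Psi \min\!\Big(\sum \Delta\varphi^C,\; \sum \Delta\varphi^E\Big).$$

The concept rule is what reproduces the reference behaviour of the worked
example below, and it guarantees $\Phi \le \min(\sum\varphi^C,
\sum\varphi^E)$: a destroyed concept can never cost more than its intact
$\varphi$. The plain difference (`delta = "plain"`) is available for
comparison; under it, a cut that merely *re-routes* a mechanism's
constraint (for instance, isolating one node so that a two-purview
constraint shrinks to a one-purview constraint) is billed only the
difference of the two $\varphi$ values, even though the surviving
constraint is about different nodes than the one the intact system
specified. Re-minimisation inside the cut system can in principle raise
$\varphi$; such negative same-purview differences are kept as computed and
logged with a warning. Minimizing-cut ties go to the first cut in
enumeration order (sources by size, then lexicographically).

## The worked example

The running example is a three-node circuit: `M` a majority gate over all
three nodes, `C` a copy of `M`, `X` the exclusive-or of `M` and `C`. Its
effective information is 2.5 bits. In state `011`:

```{r example}
mcx <- fixture_tpm("mcx")
effective_information(mcx)
comp <- composition(mcx, "011")
comp
big_phi(mcx, "011", comp = comp)
```

Every value in this table is checked against its closed form in the test
suite (for instance $\varphi^C(\mathrm{MX}) = \log_2(4/3) \approx 0.415$,
$\varphi^E(\mathrm{M}) = 1 + (1 - H(1/4)) \approx 1.189$), and the
mechanism-level search is cross-validated against an independent
brute-force enumerator that recomputes repertoires by literal summation.

## Ensembles: what the generators emulate

The samplers and enumerators generate the populations used for comparative
sweeps:

* `sample_deterministic_tpm()` draws each state's successor uniformly — the
  behaviour of a "random program" on $n$ bits;
* `sample_probabilistic_tpm()` fills the state-by-node table with
  independent Uniform(0,1) entries — heavily noise-dominated dynamics;
* `enumerate_reversible(n)` yields all $(2^n)!$ permutation systems, of
  which $(2^n-1)!$ are ergodic (a single cycle through the whole state
  space); for $n = 3$ these counts are 40,320 and 5,040, and every member
  attains the maximal effective information of 3 bits;
* `time_reverse()` maps a reversible system to its inverse permutation.

These populations emulate the *dynamical* diversity of small Boolean
systems under exact, noiseless observation of their mechanisms. They do not
emulate features of empirical recordings — sampling error in estimated
transition probabilities, non-stationarity, hidden elements, or multi-valued
units — so passing tests demonstrate correctness of the causal analysis on
exactly specified systems, not robustness of the measures under estimation
noise.

A system and its time-reverse have identical global dynamics read backwards,
yet are typically built from different mechanisms: the package's sweep
utilities make it easy to find pairs differing in total intrinsic
information or integration, which is the structural point the measures are
designed to expose. Locally, almost all Boolean gates are logically
irreversible (only copy and not are not convergent), so global reversibility
never implies that the elementary mechanisms could be run backwards.

## Problem sizes and numerical choices

All analyses in the package's tests and acceptance script run on three-node
systems (the worked example, the full reversible census of 40,320 systems
for counts and effective information) and on reduced random samples
(tens of systems) for the qualitative population comparisons: probabilistic
systems carry less total intrinsic information than deterministic ones, and
total intrinsic information and integration are positively rank-correlated.
These sizes were chosen so that each property is demonstrated by an exact
or well-sampled computation at interactive speed; the underlying functions
accept any $n$, but exhaustive enumeration is guarded at $n \le 3$ and the
partition search grows super-exponentially in mechanism size, so $n \gtrsim
6$ is impractical by design of the method, not of the implementation.

Row-stochasticity and round-trip factorisation are checked at $10^{-9}$;
probabilities are clipped to $[0,1]$ only within $10^{-12}$. The support of
a partitioned repertoire provably contains the support of the intact one
(marginalizing can only widen support), so an infinite divergence inside
the MIP search indicates a broken invariant and raises an error rather than
returning `Inf`.

## Known limitations

* Binary nodes only; the theory extends to finite-valued elements but the
  implementation does not.
* The Kullback–Leibler divergence is the only difference measure; the
  canonical framework's earth-mover's distance, the per-mechanism
  $\min(\varphi^C, \varphi^E)$ rule, purview optimisation with exclusion,
  and the search for maximally irreducible subsystems are deliberately out
  of scope.
* $\Phi$ is evaluated for the full node set as given; identifying causal
  borders of subsystems inside a larger system can be scripted with
  `big_phi()` on sub-TPMs but is not packaged.
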