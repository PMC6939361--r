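---
title: "Methods: vector-symbolic sequence binding in vsbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vector-symbolic sequence binding in vsbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsbind)
```

This vignette is the package's own account of the model it implements: the
representational algebra, the encoders built on it, every tunable that
matters, the numerical conventions, and what the synthetic benchmarks do and
do not show.

## The representational algebra

Symbols live in $\mathbb{R}^d$ as seeded random unit vectors. In high
dimension independent draws are quasi-orthogonal (pairwise cosine
concentrates around $0$ with spread $\approx d^{-1/2}$), which is the
load-bearing fact behind everything else: superpositions of unrelated
bindings interfere only weakly, and that interference — *crosstalk* — is the
model's graceful, capacity-limited mode of failure.

Four operators (the HRR algebra):

* **Superposition** is element-wise addition. The sum correlates with each
  constituent. We deliberately do not renormalize: the growing norm of an
  accumulating buffer is itself one of the model's neural predictions (see
  `activation_report()`), and an explicit `hrr_normalize()` exists for when a
  unit vector is wanted.
* **Binding** is circular convolution, computed by the FFT identity
  $a \otimes b = \mathcal{F}^{-1}(\mathcal{F}a \cdot \mathcal{F}b)$. It
  commutes, associates, and distributes over superposition; its output keeps
  dimension $d$ and is approximately orthogonal to both inputs. The test
  suite holds the FFT path to the direct $O(d^2)$ sum within $10^{-9}$
  max-abs.
* **Involution** $\neg a$ fixes entry $0$ and reverses entries $1..d-1$.
  This is the unique index permutation for which $u \otimes \neg u = e_0$
  holds exactly for unitary $u$; any other choice of "permute all but the
  first dimension" breaks the unbinding identity, which is why we commit to
  it. For generic vectors the involution is only an approximate inverse —
  unbinding returns the stored symbol plus noise.
* **Comparison** defaults to cosine (scale-invariant, required for cleanup
  over unnormalized traces); the raw dot product is exposed as well.

**Cleanup** is single-shot nearest-neighbour readout against the vocabulary.
Iterative, attractor-style refinement would be a natural extension but is
not needed at the loads exercised here. Ties break to the lexicographically
smaller name (determinism), and a best score below the threshold (default
0.1) is a distinguishable *no-match* outcome, not an error. The 0.1 default
sits an order of magnitude above background crosstalk at $d \geq 256$
(background $\sim d^{-1/2}$) yet well below the $\approx 1/\sqrt{L}$ score
of a genuine hit at the loads used in this package.

**Vector modes.** Atomic symbols default to i.i.d. Gaussian entries
($\sigma^2 = 1/d$, then normalized) — the distribution the HRR capacity
theory is stated for. A sparse mode (default density 0.05, configurable;
nothing in the theory pins the value) is provided because sparse codes are
the neurally-motivated presentation. Tag bases use the third mode,
**unitary** vectors: all Fourier magnitudes set to 1 with seeded random
phases, conjugate-symmetric so the signal is real. Unitary vectors are
exactly norm-preserving and exactly invertible under the involution, which
makes positional unbinding lossless up to superposition noise.

**Determinism.** Every stochastic draw derives a child seed from
`(global seed, purpose string, index)` through a platform-independent
polynomial hash (`child_seed()`), so a whole pipeline is bit-reproducible
from one integer, and the tag-generation scheme can be *re-instantiated*
anywhere without shipping a lookup table.

## Positional tags

Tags mark boundary-relative ordinal position. Each hierarchy level gets an
independent unitary base; tag $k$ is the $k$-th convolutional power of the
base ($2° = 1° \otimes 1°$). Powers of a random unitary vector are mutually
quasi-orthogonal; at $d \geq 256$ construction additionally screens the
family (pairwise $|\cos| < 0.2$, regenerating the base from the next child
seed up to 10 times) because unambiguous slot recovery needs near-orthogonal
keys and the theory provides no finite-$d$ guarantee. The 0.2 ceiling is a
constructive criterion chosen once: comfortably below the $\approx 0.5$
cleanup scores of true hits, comfortably above the typical
$d^{-1/2}$ coherence so regeneration is rare. Below $d = 256$ the screen is
skipped — such dimensionalities are toy scales where moderate tag coherence
is unavoidable.

Orders are 1-based ("primary", "secondary"), matching the boundary-relative
nomenclature; composite keys bind tags across levels (binding commutes, so
level order is immaterial) and `all_keys()` enumerates the full
cross-product coarse-major with the last-listed level varying fastest.

## The serial-order buffer

A sequence is $\sum_i w_i \, i° \otimes \mathrm{Item}_i$ with

$$w_i = \gamma^{L-i} + \rho^{\,i-1}, \qquad \gamma \in (0,1],\ \rho \in [0,1).$$

The $\gamma$ component is a decaying recurrent buffer (recency); the $\rho$
component is rehearsal-like input weighting (primacy). One convention
matters: the primacy term vanishes identically at $\rho = 0$ (i.e.
$0^0 := 0$ here), so that $\gamma = 1, \rho = 0$ yields the plain unweighted
superposition — the canonical encoding the hierarchical layer builds on.
Appending a token is equivalent to re-scaling the prefix: the recency part
multiplies by $\gamma$, the primacy part persists, which is how
`activation_report()` maintains the running buffer.

Defaults $\gamma = 0.82$, $\rho = 0.35$ were calibrated once to produce a
clear U-shaped serial-position curve at list length 7 with a 32-symbol
vocabulary at $d = 256$ (weights 1.30, 0.72, 0.57, 0.59, 0.69, 0.83, 1.00
across the seven positions); both are exposed. The buffer does not
renormalize between items — consistent with the accumulation prediction —
and this choice is flagged for sensitivity analysis rather than asserted as
the only possibility.

Serial recall reports sub-threshold positions as the blank token `"∅"` so
output length always equals list length.

## Dependency and hierarchical coding

Dependency encoding operates on the *salient* subsequence: irrelevant
intervening items are dropped and positions re-indexed from 1 before any
binding happens. Two consequences are exact, not statistical: `A-Xⁿ-B`
encodes bit-identically to `A-B` for every $n$, and a chunk gathered from
far-apart serial positions encodes bit-identically to the same chunk
gathered contiguously. To preserve these identities the dependency buffer
applies *no* decay weighting — decay would break them — unlike the serial
buffer upstream.

A chunk is $\sum_k k°_I \otimes \mathrm{item}_k$; a superchunk is
$\sum_c c°_C \otimes \mathrm{chunk}_c$. Nested and crossed layouts use the
identical mechanism; only the position layout in the `structure_spec`
differs. Dimensionality never grows with depth; fidelity degrades instead,
which is the intended trade (reduced representations). Two levels are
shipped; deeper recursion is available by treating a structure trace as a
token in a higher-level vocabulary.

Partial keys (e.g. `¬1°_C`) release a whole stratum; the unspecified level's
tags are then iterated to read out each slot — the constructive
interpretation of "recovers all position–item bindings". Full unpacking
iterates every key and omits no-match slots (their count is reported).

**Grammaticality familiarity.** An accumulated superposition of dependency
traces acts as a long-term memory; cosine to it is a continuous familiarity
score (thresholding is left to the caller). One subtlety is worth stating
plainly: a memory of *plain* position–item chunks stores item–position
marginals only — matched and family-mismatched A–B pairs score identically
in expectation, so pairing judgements sit at chance. The model's own remedy
is that tag bases may vary by *context*, not just level:
`encode_dependency()` keys the tag family to the dependency's governing
(first) element, so the stored trace carries co-occurrence structure and
mismatched pairings score reliably lower. This leaves `encode_chunk()` and
the bitwise identities above untouched.

**Nested vs crossed overlap.** Over the same serial tokens, nested
`{(1,4),(2,3)}` and crossed `{(1,3),(2,4)}` superchunks share their two
A-side terms out of four, so their cosine concentrates at exactly $0.5$ —
far from identity but not orthogonal. Encoded from their canonical
serializations (`A1 A2 B2 B1` vs `A1 A2 B1 B2`) the two layouts express the
*same* pairings and encode identically: representational invariance across
serializations is a design feature, and "distinguishing" nested from crossed
is a property of the position layout, not of the final trace.

## Oscillatory control

Oscillators are ideal sampled sinusoids — the functional contract
(threshold-triggered operations, antisynchronous segregation, phase-based
position coding) needs nothing more, and spiking substrates are out of
scope. Conventions: time is unitless integer steps; a trigger fires at an
upward threshold crossing (`a(t-1) <= θ < a(t)`); the antisynchronous
partner is offset by π with nearest-sample rounding, and the two streams
never share a time step (checked exhaustively for all periods up to 200
steps). Phase maps to position by $1 + \lfloor K\phi/2\pi \rfloor$ over $K$
equal bins.

`gated_encode()` commits each token at the first trigger at or after its
onset and decodes its order from a positional oscillator at `freq/K` whose
phase is referenced to the first commit — so consecutive triggers advance
exactly one position bin. The anchoring choice makes the dynamic/static
equivalence exact (bit-identical traces) whenever stimuli are entrained to
the gate, i.e. each token commits at the next trigger after its
predecessor's; the shared accumulation core guarantees the identity at the
floating-point level. Tokens colliding on one trigger or one position bin
raise an error rather than queueing — queueing would silently break the
equivalence contract. Trigger events all fall at a fixed phase of the
driving oscillation (`phase_concentration()` ≈ 1), the functional reading
of phase–amplitude coupling.

## Synthetic grammars and what the benchmarks show

The generators emit the four paradigm families — adjacent pairs, `A-Xⁿ-B`
with family-matched (grammatical) or family-mismatched (ungrammatical)
pairings, and nested/crossed $k$-pair layouts — deterministically under a
seed. The ungrammatical construction is the standard violation type
(mismatched pairing, not random tokens). Defaults follow the worked
paradigms: 2 pairs for hierarchical layouts, 2 intervening items for
`A-Xⁿ-B`, 4–8 families, 32-symbol vocabularies for recall benchmarks, 50
training exemplars for familiarity.

These are idealizations. The generators emulate the *structure* of
artificial-grammar stimuli, not their sensory front end: tokens arrive
pre-discretized and pre-identified, dependencies are declared rather than
parsed, and vocabulary items are exactly orthonormal in expectation rather
than perceptually graded. Passing benchmarks therefore demonstrates the
representational claims (capacity scaling, boundary-relativity, key-based
retrieval, familiarity separation) — they say nothing about segmentation,
dependency discovery, or learning, all of which are upstream of this model.

Problem sizes in the shipped tests — e.g. 200-seed round-trips at
$d = 1024$, 500-trial serial-position curves at $d = 256$, 1000-trial
recovery runs — were chosen as the smallest Monte-Carlo sizes at which the
binary properties are stable to re-seeding; the benchmark functions accept
larger values.

## Numerical conventions and degenerate inputs

* "Exact" claims mean $10^{-9}$ max-abs at $d \leq 1024$ in double
  precision (measured headroom is far larger; unitary round-trips land near
  $10^{-15}$).
* Empty token list → a zero trace of length 0; recall on it is an error,
  serial recall returns an empty vector. A zero vector cleans up to
  no-match (cosine to everything is treated as 0) and cannot be normalized.
* `superpose([A])` returns `A` unchanged; `bind(e₀, x) = x`.
* Cleanup threshold default 0.1; pass `threshold = -1` to force a best
  guess (used when measuring raw accuracies).
* Serialization is a JSON sidecar plus a `%.17g` tab-separated matrix,
  which round-trips IEEE doubles bit-exactly; vocabulary and tag-set
  sidecars carry their generation parameters, so containers are
  self-describing and regenerable.

## Known limitations

* Cleanup is single-shot; no attractor iteration.
* Two hierarchy levels are wired in; deeper nesting requires explicit
  re-tokenization of traces.
* Item-level salience masks only; n-gram-level inhibition is noted as an
  extension, not implemented.
* Single-band gating: stimulus rates above the gate rate are an error, not
  a nested fast/slow scheme.
* No learning: tag generation and vocabularies are deterministic givens;
  acquiring them is outside the model's scope.
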