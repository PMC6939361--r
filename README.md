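# vsbind

Vector-symbolic sequence binding with holographic reduced representations.

## What this is for

How can a neural system represent *structured* sequences — not just which
items occurred, but which item occupied which position, which items depend on
which, and how those dependencies nest or cross — using fixed-width
distributed codes? `vsbind` implements a computational account of this
problem aimed at researchers in computational neuroscience and cognitive
modelling who study serial-order working memory, chunking and
artificial-grammar learning. It provides the representational algebra, the
sequence and dependency encoders built from it, an oscillatory scheduling
layer, and synthetic grammar generators with Monte-Carlo capacity
benchmarks, all deterministic under a single seed.

## The model

Symbols are high-dimensional random unit vectors (quasi-orthogonal by
construction). The algebra is Plate's holographic reduced representation
(HRR):

* **superposition** `A + B` — element-wise addition; the result is
  correlated with both inputs;
* **binding** `A ⊗ B` — circular convolution,
  `(A ⊗ B)[k] = Σⱼ A[j]·B[(k−j) mod d]`; the result keeps dimensionality d
  (a *reduced representation*) and is approximately orthogonal to both
  inputs;
* **unbinding** `(A ⊗ B) ⊗ ¬B ≈ A + noise`, where `¬` is the involution
  that fixes entry 0 and reverses the rest — exact when the key is
  *unitary* (all Fourier magnitudes 1);
* **cleanup** — nearest-neighbour cosine readout against a vocabulary.

On top of the algebra:

* **Positional tags.** Ordinal positions 1°, 2°, … are convolutional powers
  of a unitary base (`2° = 1° ⊗ 1°`), one independent base per hierarchy
  level (items, chunks). Tags are boundary-relative: they encode position
  within a chunk, never absolute time.
* **Serial-order buffer.** `Sequence = Σᵢ wᵢ · i° ⊗ Itemᵢ` with
  `wᵢ = γ^(L−i) + ρ^(i−1)` — recency by decay, primacy by input weighting —
  reproducing the U-shaped serial-position curve. Retrieval is
  `Item ≈ Sequence ⊗ ¬i°` plus cleanup.
* **Dependency coding.** Salience filtering drops irrelevant intervening
  items, so `A-Xⁿ-B` encodes *bit-identically* to `A-B`. Chunks
  `Σₖ k°_I ⊗ itemₖ` bind to chunk tags and superpose into superchunks,
  `Σ_c c°_C ⊗ chunk_c`, covering nested and crossed dependencies with one
  mechanism. Composite keys such as `¬(2°_I ⊗ 1°_C)` retrieve single slots;
  iterating all tags unpacks the whole structure.
* **Oscillatory gating.** Thresholded sinusoids trigger discrete binding
  operations; antisynchronous oscillators segregate operation streams;
  oscillator phase decodes to ordinal position. Gated encoding is
  bit-identical to static encoding — scheduling changes *when*, never
  *what*.

## Worked example

Encode the nested sequence A1 A2 B2 B1 (outer pair A1–B1, inner pair A2–B2)
and query it:

```r
library(vsbind)
voc <- hrr_vocabulary(c("A1","A2","B1","B2"), dim = 1024, seed = 7)
it  <- make_tagset("item",  1024, max_order = 2, seed = 7)
ch  <- make_tagset("chunk", 1024, max_order = 2, seed = 7)

sp <- structure_spec(list(c(1, 4), c(2, 3)), kind = "nested")
st <- encode_structure(c("A1","A2","B2","B1"), sp, voc, it, ch)

# "the second item of the first chunk": key ¬(2°_I ⊗ 1°_C)
key <- invert_key(compose_key(list(it, ch), c(item = 2, chunk = 1)))
query_structure(st, key, voc)[[1]]
#> <cleanup> B1 (score 0.513, runner-up 0.036)

unpack_structure(st, voc, it, ch)
#>   chunk item name     score
#> 1     1    1   A1 0.5256974
#> 2     1    2   B1 0.5125059
#> 3     2    1   A2 0.5127383
#> 4     2    2   B2 0.5696552
```

The query releases B1 — the outer chunk's closing element — with a cleanup
score far above the runner-up; the full unpack recovers all four
(chunk, item, token) triples. Scores sit near `1/√L ≈ 0.5` because the trace
superposes four quasi-orthogonal bindings: crosstalk, the model's
characteristic lossiness, grows with load and shrinks with dimensionality.

Serial memory works the same way at one level:

```r
tg <- make_tagset("item", 1024, 3, seed = 7)
tr <- encode_sequence(c("A1","B2","A2"), voc, tg, gamma = 1, rho = 0)
serial_recall(tr, voc, tg)
#> [1] "A1" "B2" "A2"
```

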