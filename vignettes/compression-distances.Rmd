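---
title: "Compression distances and phylogenies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression distances and phylogenies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdphylo)
```

## What the package computes

`ncdphylo` compares genomic sequences — or whole short-read samples —
without assembly, without alignment, and without data-dependent tuning
parameters. The only primitive is a compressor: writing `C(x)` for the
compressed size of a payload `x` in bytes, `C(xy)` for the size of the
concatenation and `C(x|y)` for the size of `x` when the compressor's
model has first been trained on `y`, three dissimilarities are defined:

* the compression dissimilarity measure,
  `d_CDM(x, y) = C(xy) / (C(x) + C(y))`, ranging from 1/2 (identical
  inputs) to 1 (inputs sharing no information);
* the conditional-compression distance,
  `d(x, y) = (C(x|y) + C(y|x)) / C(xy)`, ranging from 0 to 1;
* the normalized compression distance,
  `d_NCD(x, y) = max{C(x|y), C(y|x)} / max{C(x), C(y)}`, a computable
  stand-in for the (uncomputable) normalized information distance and a
  proper metric under an idealized compressor.

A set of samples yields a labeled distance matrix
(`pairwise_distances()`), the matrix yields a neighbor-joining tree
(`neighbor_joining()`), and trees are scored against a reference
topology (`rf_symmetric_difference()`) or against a true classification
of the leaves (`parsimony_score()`). An NGS sample enters the pipeline
by concatenating its reads into one payload (`sample_from_reads()`).

## The built-in coder

Any compressor can stand behind the distances
(`compressor_backend("gzip")` etc. use `memCompress()`), but generic
compressors cannot be trained on a conditioning sequence, so for them
`C(x|y)` falls back to the standard approximation
`max(C(yx) - C(y), 0)` and is flagged approximate. The built-in backend
is a bespoke coder with a true conditional mode. Its design:

* **Alphabet.** `{A, C, G, T, N}`; `sanitize()` maps U to T and every
  other IUPAC ambiguity code to N, preserving payload length so read
  counts and coverage stay meaningful.
* **Model.** A mixture of experts. Experts 0..k are frequency tables
  over contexts of the last 0..k symbols (default `context_order`
  k = 8), each predicting with pseudocount 1/8 and abstaining while its
  context is unseen. One further *match expert* maintains a rolling
  hash of every 10-mer seen so far; once an exact 10-mer match anchors
  it to an earlier position, it predicts the symbol that followed the
  anchored position with an adaptively estimated hit probability `q`
  (decayed success/failure counts, drop when clearly dead), spreading
  `1 - q` over the other symbols in proportion to the context experts'
  own prediction. Because the hash spans the conditioning sequence as
  well, this expert is what recognizes positional homology between `x`
  and `y` rather than mere compositional similarity. Expert weights are
  updated multiplicatively by predictive success with a small uniform
  mixing floor.
* **Coding.** Classic 32-bit arithmetic coding with underflow
  (pending-bit) handling. Mixture probabilities are quantized to a
  14-bit total with every symbol kept at frequency at least 1, encoder
  and decoder quantizing identically, so decoding is exactly lossless.
* **Bitstream.** An 8-byte big-endian symbol count, then the coded
  payload, then 32 padding bits. The padding covers the decoder's
  32-bit pre-read, so a valid stream is never read past its end and any
  overrun proves truncation or corruption (truncations of six or more
  bytes are detected structurally; sub-byte slack means a 1-byte
  truncation can occasionally decode to a wrong payload undetected).
* **Sizes.** `C(x) = ceiling(code bits / 8) + 8` header bytes.
  `C(x|y)` primes the model with one pass over `y` (statistics updated,
  nothing emitted), resets the local context windows, then codes `x`;
  the reported size is `min(primed bits, unprimed bits) + 1` flag bit,
  so `C(x|y) <= C(x) + header` holds by construction, not merely on
  average.

### Why not a single fixed-order model

A fixed-order table (say order 6) over a 5-letter alphabet has 15,625
contexts and cannot warm up inside a few kilobases: on uniform random
DNA it spends near `log2(5) = 2.32` bits/base instead of approaching
the 2-bit entropy floor. The order mixture adapts from order 0 upward
and approaches the entropy floor quickly: the test suite asserts `C(x)`
for a 4,000-base uniform payload lies in [950, 1100] bytes, i.e. within
a few percent of 1,000. Conversely, context statistics alone are blind
to *positional* homology: two genomes at 0.4+ substitutions/site have
almost identical k-mer statistics relative to their divergence, and a
pure context mixture saturates. The match expert supplies that signal;
the test suite verifies that all three measures strictly order
Jukes–Cantor divergences 0.01 < 0.05 < 0.20 and that compressing a
sequence conditioned on itself costs under half — in practice a few
percent — of its unconditional size.

### Parameter defaults and how they were chosen

All constants are frozen in the coder and none is fitted to data at run
time — the method stays parameter-free for the user. `context_order = 8`
was chosen on synthetic calibration runs (entropy on uniform data,
identity compression, divergence discrimination), trading a memory cost
of about 10 MB of count tables for better modeling than lower orders.
The match-seed length 10 balances sensitivity and specificity: at high
divergence two homologs of a few tens of kilobases still share exact
10-mers (enough to anchor), while random 10-mer collisions are rare
enough for the hit-rate estimate to discard false anchors quickly. The
quantization total (2^14), pseudocount (1/8), count-rescale threshold
(16,000), weight floor (1/64) and match decay (0.98) were likewise set
on calibration runs independent of any test data.

## Distance-matrix conventions

Compressors are order-sensitive but the matrices must be symmetric, so
the joint payload of a pair is always concatenated in canonical order
(sorted by label); `C(x)` is computed once per sample and cached. The
diagonal is stored as 0 by convention — the PHYLIP-style toolchain
downstream expects zero self-distance — even though the raw CDM
self-value is about 1/2 (the scalar functions `dist_cdm()` etc. remain
available for raw values). `matrix_correlation()` flattens both
matrices by concatenating rows (diagonal and both triangles included by
default, with an option to restrict to the upper triangle) and returns
the Pearson correlation.

## Phylogenetic evaluation

`neighbor_joining()` wraps the standard Q-criterion agglomeration
(`ape::nj`) behind input validation; on an additive matrix it provably
recovers the generating topology, which the tests verify on random
additive matrices. `rf_symmetric_difference()` counts the bipartitions
present in exactly one of the two trees (both directions, so values are
even for binary trees). `parsimony_score()` implements the bottom-up
leaf-label rule: each internal node takes the intersection of its
children's label sets when non-empty, otherwise their union at a
penalty of 1; a tree in which every group of the true classification is
monophyletic scores `g - 1` for `g` groups. The score equals the Fitch
parsimony length of the group character, is invariant to rooting
(tested exhaustively), and equals `g - 1` exactly when the groups span
node-disjoint subtrees — a slightly weaker condition than monophyly,
which the test suite characterizes precisely.

## Synthetic data: what it shows and what it cannot

`simdata` generates every test input: i.i.d. random genomes
(`random_genome()`), Jukes–Cantor evolution along a guide tree
(`evolve_along_tree()`, per-site substitution probability
`(3/4)(1 - exp(-4d/3))` for branch length `d`), and a short-read
simulator (`simulate_reads()`) with uniform start positions, fixed read
length (default 100), depth-derived read counts, and uniform
substitution error models standing in for platform profiles
(`illumina_like` 0.01/base, `sanger_like`/`ls454_like` 0.005/base,
`exact` error-free).

These generators are deliberately transparent rather than realistic:

* No indels and no rearrangements — homologous positions stay aligned,
  which favors any method sensitive to positional homology. Passing the
  recovery experiments here demonstrates correctness of the pipeline,
  not performance on real genomes with structural variation.
* Substitution-only, uniform error models; no quality-score
  information, GC bias, or paired-end structure.
* Forward-strand reads by default (an option flips strands), keeping
  the exact-model substring invariant testable.

## Observed behavior and limitations

The following are measured by the test suite and the acceptance
experiments, not asserted from theory:

* Neighbor joining on NCD/CDM matrices of ten 20-kb genomes evolved
  along a random guide tree (branch lengths 0.02–0.3) recovers the
  topology to within a Robinson–Foulds difference of 2. The tolerance
  is information-limited rather than slack: the NCD transform is
  concave in path length, so even exact distances pushed through an
  ideal compressor's transform yield a non-additive matrix on which NJ
  can lose one deep, short split.
* Matrices computed from 5x read samples correlate with genome-derived
  matrices at Pearson r above 0.9, and NCD matrices are robust to the
  read-concatenation order (pairwise r above 0.99 across shuffles).
* Distances saturate near 1 beyond roughly one substitution per site;
  deeper divergences are not resolvable.
* The coder is subadditive (`C(xy) <= C(x) + C(y)`) on random and on
  related pairs across the tested scales, but degenerate concatenations
  (a constant sequence followed by a random one) can exceed the bound
  by a model-transition cost, so CDM can marginally exceed 1 in
  pathological mixtures.

## A small worked example

```{r example, eval = FALSE}
library(ncdphylo)

guide <- random_guide_tree(6, seed = 42)
genomes <- evolve_along_tree(random_genome(10000, seed = 43), guide,
                             seed = 44)
d <- pairwise_distances(sample_set(genomes), measure = "ncd")
tree <- neighbor_joining(d)
rf_symmetric_difference(tree, guide)
```

The command-line interface in `inst/cli/ncdphylo.R` exposes the same
pipeline (`dist`, `nj`, `root`, `treedist`, `parsimony`, `corr`,
`simreads`, `evolve`, `randgenome`) over FASTA/FASTQ inputs and
PHYLIP/Newick outputs.
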