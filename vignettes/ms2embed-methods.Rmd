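---
title: "Methods: self-supervised spectrum embeddings at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised spectrum embeddings at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ms2embed implements, end to end and at sizes a laptop can run, a
self-supervised learning stack for tandem mass spectrometry: quality-controlled
mining of LC-MS/MS runs into a tensor store, locality-sensitive-hash (LSH)
deduplication, scaffold-aware dataset splitting, a transformer encoder over
spectral peaks trained by masked-peak and retention-order objectives,
fine-tuning heads for annotation tasks, and a similarity-graph atlas over the
resulting embeddings. This vignette records the model, the assumptions, and
every numerical choice a maintainer would want to know.

## Spectra as data

A spectrum enters the model as the 2 x (n+1) matrix whose first column is the
precursor token `(m0, 1.1)` and whose remaining columns are up to `n` peaks as
(m/z, relative intensity) pairs. The sentinel intensity 1.1 lies deliberately
outside the `[0, 1]` range of relative intensities, letting the network
recognize the aggregation token without positional encoding. When a spectrum
has more than `n` peaks the `n` most intense are kept (ties broken toward
lower m/z); fewer are zero-padded and masked out of attention. Relative
intensity is taken against the base peak of the spectrum. Peaks are ordered by
ascending m/z after the precursor column; the encoder is
permutation-equivariant, so this ordering only pins down reproducibility.

## Quality control

File-level checks reject runs with unordered retention times, invalid MS-level
sequences, no MS1 data, or fewer than three spectra. Instrument accuracy is
estimated from MS1 data in two XIC rounds: base-peak m/z values seed extracted
ion chromatograms at 0.5 Da tolerance; XICs with at least five points
contribute their median m/z as second-round seeds at 0.01 Da; the estimate is
the median of per-XIC standard deviations, and it is *undefined* (never zero)
when no second-round XIC reaches five points. A peak joins an XIC if it is the
closest in-tolerance peak in its scan, scanning in order; seeds are
deduplicated within the round's tolerance.

Spectrum-type classification inspects the full-width-at-half-maximum window
around the base peak. As printed, the original set-builder for the window is
vacuously satisfied below the base peak; we implement the evident intent — the
maximal contiguous index run containing the base peak with intensities above
half the base intensity. A window spanning fewer than 3 indices, or wider than
a thousandth of the spectrum's m/z span, indicates centroided sticks;
otherwise zeros indicate raw profile data and their absence thresholded
profile data.

Three spectrum-level quality tiers ship as presets (A strictest: at least 5
peaks, intensity amplitude at least 10, single positive charge, precursor at
most 1000 Da, centroided, estimated accuracy at most 1e-3 Da). The source
description fixes the criteria but not every numeric threshold; the B and C
relaxations (B: 3 peaks, amplitude 2, no accuracy bound; C: additionally
allows unknown charge and non-centroided peaks) are this package's documented
assumptions, fully overridable, and constructed so the tiers nest.

## LSH deduplication

Spectra are binned onto half-open 1 Da windows over `[0, 1000)` Da
(intensities summed per bin, no normalization — the hash is sign-based and
cosine similarity is scale-free) and hashed against `m` standard-normal
hyperplanes; bit k is 1 exactly when the k-th dot product is `>= 0` (zero
hashes to 1). Two presets ship: 64 hyperplanes (deduplication) and 30
(subset construction). Spectra sharing a key form a cluster; a seeded uniform
sample of at most `cap` members is retained. The per-hyperplane collision
probability at cosine similarity `c` is `1 - acos(c)/pi`, which the test
suite verifies by Monte Carlo at several `c` and `m`.

## Murcko-histogram splitting

Fine-tuning folds must separate not just identical structures but whole
scaffold families. A molecule's Murcko scaffold (terminal atoms iteratively
pruned) is summarized as a histogram over its rings: each
smallest-set-of-smallest-rings ring with more than 3 atoms is binned by
`(r, l)` where `r` counts fused neighbors (half the shared-atom count with all
other rings, accumulated exactly and floored, so spiro contacts contribute 0)
and `l` counts adjacent linker atoms (non-ring scaffold atoms of degree above
one — the literal ring-and-linker intersection in the printed procedure is
always empty, so we implement the stated intent). Two molecules are related
when either has fewer than `k = 4` rings and the histograms are identical, or
the L1 distance between their ring marginals is below `m = 5`.

Splitting groups molecules by identical histogram, assigns groups to
validation under a seeded shuffle while they fit below the target fraction,
then iteratively relocates any validation group related to a training group
until a fixed point: no related pair ever crosses folds, and a library with a
single histogram group keeps validation empty rather than leak. The initial
assignment heuristic is ours (the published text does not fix one).

Because no R toolkit exposes a cheminformatics kernel in this stack, SMILES
parsing is delegated to OpenBabel via ChemmineR/ChemmineOB, and ring
perception (SSSR via shortest cycles with GF(2) independence), the 4096-bit
radius-2 circular fingerprint, and 11 graph-computable property descriptors
(monoisotopic weight, heavy atoms, rings, rotatable bonds, H-bond donors and
acceptors, halogens, heteroatom fraction, sp3 carbon fraction, branching
index, size-complexity) are authored in this package. The fingerprint plays
the Morgan role in splitting and retrieval experiments but is not
bit-compatible with external toolkits, and the property list is our
substitution for the partially printed original list — both labeled
assumptions.

## The encoder

Each m/z value is expanded into mass-tolerant Fourier features
`sin/cos(2 pi b_i m)` on a fixed frequency grid: reciprocals of integers
`m_max..1` (the low block, capturing integer mass), then `1/(k m_min)` for
`k = 1, 1+s, ...` up to `1/m_min` (the high block, capturing decimal mass down
to the instrument accuracy). With `m_min = 1e-4`, `m_max = 1000` the printed
grid has 1000 low and 5000 high frequencies; a literal enumeration of every
`k` would give 10000 high frequencies, so the stride `s = 2` is adopted as the
reading that reproduces the printed 5000 and makes the block end exactly at
`1/m_min`. A 4-layer feed-forward net (hidden width `2 d_m`, our default — the
original hidden widths are unprinted) maps the features to `d_m = 980`
dimensions, concatenated with a small net on the raw (m/z, intensity) pair
(`d_p = 44`) to give `d = 1024` per peak.

Seven pre-norm transformer layers (8 heads, ReLU, no linear biases) exchange
information between peaks. Attention scores receive an additive
Graphormer-style bias: the summed difference of the two peaks' Fourier
features, an antisymmetric matrix that exposes exact m/z differences (neutral
losses) to every layer; the bias is added before the `1/sqrt(d)` scaling. The
summation limit over feature components is not defined in the source ("2t");
we default to all `2B` components and expose it as configuration. The bias is
shared across heads (the text implies an unlearned sum). Padded columns are
excluded from attention as keys and from every loss. A final layer norm
produces the output representations; the precursor token's row is the
spectrum embedding. With the reference configuration the parameter count lands
at ~1.5e8, the same order as the published ~1.16e8; exact equality is not
claimed because hidden widths are unprinted.

Output heads: a `c`-way softmax per masked peak for mass reconstruction, a
sigmoid on two concatenated precursor embeddings for retention order, linear
heads on the precursor embedding for 11 properties, fluorine probability and
the contrastive embedding, and a DeepSets-style two-layer head summed over all
peak representations for 4096 fingerprint activations.

The network, its analytic backward pass and the Adam optimizer are written in
plain R matrix code — the architecture is the package's subject matter, and
the gradient of every block is verified against central finite differences in
the test suite.

## Self-supervision

Each training example is a pair of spectra from one run. 30% of each
spectrum's real peaks are masked — sampled without replacement proportionally
to intensity (successive draws with renormalization) — by replacing m/z with
the sentinel -1.0 (which flows through the Fourier features unchanged) while
keeping intensities; the precursor token is never masked. True masses are
discretized into `c` equal-width half-open bins over `(0, 1000)` Da
(`c = 20000` at full scale). The mass loss sums the cross-entropy over each
spectrum's masked peaks and averages the two spectra; the order loss is binary
cross-entropy on predicting whether the second spectrum elutes later; the
total weighs them 0.8/0.2. Batch reduction is the mean over pairs (unstated in
the source; declared here). With probability 0.2 a spectrum is augmented by
one uniform m/z shift from (0, 50) Da applied to all columns including the
precursor, preserving all pairwise differences.

Linear probing freezes the encoder and fits one logistic layer from precursor
embeddings to binary structure labels, reporting the best validation recall
within the epoch budget and its matching precision; degenerate all-zero bits
are excluded.

## Fine-tuning

Contrastive similarity training mines triplets: the positive shares the
reference's molecule identity key; the hard negative is a different molecule
within 0.05 Da precursor mass. The hinge `max{cos(z, z-) - cos(z, z+) + 0.1, 0}`
is used: the printed form has the cosine terms transposed, which would push
references *away* from positives, so the stated intent is implemented (and the
printed fingerprint objective is likewise a similarity; we minimize
`1 - cos`). Cosines carry a `1e-8` stability floor on the norm product.
Properties are min-max scaled by training-fold statistics only and fit under
mean squared error over the 11 targets; fluorine uses the focal loss
`-alpha_F (1 - p_F)^gamma log p_F` with `alpha = 0.8`, `gamma = 0.5` (equal to
half the standard BCE at `gamma = 0`, `alpha = 0.5`). Fine-tuning asserts
Murcko-disjoint folds before touching the data and early-stops on a
validation-metric plateau, returning the best-validation weights.

## Atlas

Embeddings are joined into a directed 3-NN graph under cosine similarity. At
desk scale the neighbors come from exact vectorized search — the approximate
NN-Descent stage of the repository-scale original is deliberately not
re-implemented, since the package's contract (exact agreement with brute force
at these sizes) makes the approximation pointless here. Neighborhoods are
collapsed by BFS from each still-unassigned node, iterating nodes in
descending out-degree (constant `k` in a pure k-NN graph, so effectively node
id — the deterministic tie-break); expansion over an edge stops when the edge
similarity or the start-to-candidate similarity falls below 0.9. The graph is
then rebuilt on the representatives' own embeddings (not centroids). Blank
samples are excluded by the standard filename markers, case-insensitively.

## The synthetic data generator

All tests run on generated data, so the generator *is* the study condition.
A seeded fragment vocabulary (60 masses uniform over 80-900 Da) is carved
into contiguous per-molecule windows, making fragment co-occurrence
deterministic: observing a spectrum's unmasked peaks identifies the molecule
and hence the masked masses — masked-peak prediction is information-
theoretically solvable, which the desk-scale learning checks require. MS1
scans carry a base peak at 500 Da jittered by a configurable sigma (the
jitter multiplies a seed-fixed standard-normal draw, so the accuracy estimate
is exactly monotone in sigma across runs). MS2 peak shapes reproduce the
structural signatures of the three spectrum types; molecules elute in blocks
under a monotone retention model so order labels are learnable; noise peaks
sit below the 10th percentile of signal intensity. The annotated library
builds real, parseable molecules from six scaffold cores decorated with
varying substituents, computes fingerprints/properties/fluorine flags from
the structures, plants same-nominal-mass decoy pairs 0.02 Da apart for hard
negatives, and allocates exactly the requested fluorinated fraction.

What the generator does not emulate: physically realistic CID fragmentation,
isotope envelopes, chimeric spectra, adduct heterogeneity within a molecule,
or instrument-specific intensity response. Passing tests therefore
demonstrate the correctness and trainability of the machinery, not
benchmark-level annotation accuracy on real libraries.

## Desk-scale problem sizes and numerical choices

The test suite and the acceptance script use: a tiny encoder (d = 64, 2
layers, 4 heads, c = 1000 bins, 30-peak inputs, reduced Fourier grid
`m_min = 0.01`, `m_max = 100`) pre-trained for 500 steps with batch size 16
and Adam at learning rate 3e-3 on ~2000 generated spectra over 3 seeds —
sizes chosen so the full stack trains in minutes on one CPU while still
beating the uniform-prediction baseline `ln c` and exceeding ten times chance
top-1 accuracy on masked bins. The full-scale defaults (d = 1024, 7 layers,
c = 20000, learning rate 3e-4, batch 64, constant schedule) ship as documented
configuration; the original schedule tables are not public, so these are the
package's own defaults. Layer norm uses eps 1e-5; probability outputs are
clamped at machine epsilon before logs; the masked-bin label at the upper
range edge is clipped into the last bin.

Known limitations: no vendor raw-file support; no recalibration; exact
(not approximate) neighbor search; single-device training only; the
fingerprint and property descriptors are package-defined stand-ins for
toolkit-specific ones.
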