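---
title: "Learning protein sequence–function maps from deep mutational scanning data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning protein sequence–function maps from deep mutational scanning data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dms2func)
```

## The problem

A deep mutational scan (DMS) couples a high-throughput functional selection
with sequencing, yielding thousands to millions of protein variants, each
with a quantitative functional score (typically a log enrichment ratio
between post- and pre-selection read counts). `dms2func` treats the scan as a
supervised regression problem: learn $f(\text{sequence}) \to \text{score}$
from the scored variants, then use the trained model to predict unseen
variants, interpret which residues drive function, and design new sequences.

A variant is a set of substitutions against a fixed wild type, written in the
usual notation (`"E19Q,A24Y"`; the empty string is the wild type itself).
Positions are 1-based, substitutions are canonically ordered by position, and
the stop symbol `*` is allowed only as a mutant letter.

## Encoding

Each residue is encoded as a length-$(21 + d)$ feature vector: a one-hot
block over the 21-letter alphabet (20 amino acids in fixed alphabetical
order, then stop) concatenated with a $d$-dimensional PCA projection of an
amino-acid physicochemical property table, and a variant is the $L \times
(21+d)$ stack of its residue vectors. Because a property table has only 20
rows, its centered rank is at most 19, so $d = 19$ always captures 100% of
the property variance; this is the default.

Numerical choices, made once and fixed:

* properties are standardized (zero mean, unit variance per column) before
  PCA; zero-variance columns are dropped with a warning;
* the PCA is fitted on the 20 standard amino acids only, and `*` receives
  the zero property vector (there is no physicochemistry for a stop);
* each component's sign is set so its largest-magnitude loading is positive,
  making encodings bit-identical across platforms.

The packaged property table (`inst/extdata/aa_properties_synthetic.csv`) is
a **synthetic** stand-in with the shape of a curated property database
(20 amino acids × 30 properties, a few columns anchored on familiar
hydropathy/volume/charge scales plus correlated noise columns). Any real
property table with the same layout can be dropped in via
`read_property_matrix()`.

## The four architectures

All models map the encoded variant to one scalar and are trained identically:

* **linear** — a single dense layer over the flattened encoding. Strictly
  additive across positions; its double-mutant prediction is exactly the sum
  of its single-mutant effects, which makes it both a baseline and an
  analytic oracle for tests.
* **fully connected** — dense hidden layers (default one layer of 100
  units), each followed by leaky-ReLU and 20% dropout, then one output node.
* **sequence convolutional** — 1-D convolutions slid along the sequence with
  stride 1 and *no padding* (a kernel of width $k$ leaves $L-k+1$ positions),
  then a flatten, a 100-unit dense layer with leaky-ReLU and dropout, and the
  output node.
* **graph convolutional** — the order-independent operator on a residue
  graph: for center node $i$ with neighbors $N_i$,
  $$z_i = \sigma\!\left(W_C^\top x_i + \frac{1}{|N_i|}\sum_{j \in N_i} W_N^\top x_j + b\right),$$
  with one shared neighbor weight matrix $W_N$ (all neighbors are treated
  identically and their incoming signal is averaged) and a per-node output,
  so graph structure is preserved across stacked layers. Nodes with no
  neighbors simply drop the neighbor term — this convention is what makes
  the disconnected baseline graph well defined, and it reduces the layer to
  a per-position dense transform (numerically identical to a width-1
  sequence convolution, which the tests check).

Leaky-ReLU uses a fixed negative slope of 0.2. Initialization is a seeded
uniform fan-in scheme, so two builds from the same spec are identical.
Dropout is active only during training; prediction is deterministic.

The residue graph comes from a structure: Euclidean distances between
β-carbons (α-carbon for glycine, standard contact-map practice) are
thresholded at a hyperparameter in the 4–10 Å range. The comparison is
*closed* (≤), a choice that must be fixed for bit-exact graphs. Four
deliberately misspecified baselines (shuffled, disconnected, sequential,
complete) let one measure how much real structure contributes.

## Training and evaluation

Training minimizes mean squared error with Adam (defaults except the
learning rate and batch size, which are the tunable knobs) and epoch-level
early stopping: stop after 15 epochs without a tuning-loss improvement of at
least $10^{-5}$, cap at 300 epochs, and restore the best-epoch parameters.
The tuning loss is the exact unweighted mean over tuning examples (a known
quirk of early implementations of this pipeline overweighted the last
minibatch; here the mean is exact).

Splits:

* **random** — 81% train / 9% tune / 10% test, floors to tune/test and the
  remainder to train so training is never starved;
* **mutational extrapolation** — 80% of the *distinct single mutations* are
  designated training; variants carrying only training mutations form the
  train+tune pool (90/10), variants carrying only testing mutations form the
  test set, and mixed variants are discarded, so the train/test mutation
  sets are provably disjoint;
* **positional extrapolation** — the same construction over mutated
  *positions*;
* **reduced-size** — five seeded replicates per size drawn from the training
  pool only, summarized by the median.

Beyond correlation and MSE, the ranking metrics mirror protein-engineering
use: `recall_at_budget()` (what fraction of the true top-100 variants a
model's top-$N$ picks recover), `top_n_stats()` (mean and max true score of
the top-$N$ predictions) and `random_baseline()` (1,000 random rankings,
95% band at $\pm 1.96$ SD; the expected recall of a random ranking at budget
$N$ is $N/|\text{test}|$). Prediction ties are broken by variant index, so
every metric is deterministic. Zero-variance predictions yield `NaN`
correlations with a warning rather than a silent 0.

## The resampling simulator

Raw DMS data are paired read counts (input and selected pools). Scores are
wild-type-normalized natural-log ratios with 0.5 pseudocounts:
$$s(v) = \ln\frac{c_\text{sel}(v)+0.5}{c_\text{inp}(v)+0.5} -
         \ln\frac{c_\text{sel}(wt)+0.5}{c_\text{inp}(wt)+0.5}.$$
This replaces the external scoring tool the original analyses call; the
package's claims are internal-consistency claims, not byte-compatibility
with that tool.

`resample_dataset()` draws a library uniformly without replacement, splits a
read budget between pools by the base dataset's read fractions
(deterministic rounding conserves the budget exactly) and samples counts
from multinomials proportional to the base counts. `run_grid()` sweeps
library size × read budget (five replicates per cell, cells with fewer than
25 scored variants in any replicate are excluded as data, not errors),
retrains a model per replicate and evaluates against held-out,
*non-resampled* scores — test variants are removed from the base before any
library is drawn, so leakage is impossible by construction. The emergent
picture is the library-size/read-depth trade-off: at a fixed budget there is
an optimal intermediate library size.

## Interpretation

`integrated_gradients()` distributes $f(x) - f(x')$ over input features by
integrating the input gradient along the straight path from a baseline
$x'$ (the wild-type encoding, so attributions read as contributions of
mutation-induced feature changes). The Riemann sum uses the **midpoint
rule** — at equal step counts it converges faster than the left/right rules,
and the completeness error shrinks monotonically with steps (tested at 10,
100, 1000). For the linear model the attribution is exactly
$w \odot (x - x')$, an analytic oracle. Per-position sums aggregate the
$L \times (21+d)$ attribution matrix to one value per residue, and summing
over a training set gives a per-position importance profile. Attributions
over the one-hot and property blocks are summed jointly.

`latent_representations()` exposes the activations feeding the output node
(length 100 for the default convolutional head); the linear model has no
internal layer and is rejected. `single_mutant_matrix()` fills the complete
$L \times 21$ prediction map — including stop and mutations absent from
training data, which parameter-sharing models can still score.

## Sequence design

`hill_climb()` searches $S_n$, the set of sequences exactly $n$ mutations
from the wild type, for the maximizer of the *minimum* predicted score over
a model ensemble — a conservative objective that only rewards sequences all
models agree on. Moves "exchange" one substitution: delete one of the $n$
current substitutions, then add one substitution at any position left
unmutated (including re-mutating the vacated position to a different
letter). Changing the letter at another still-mutated position is excluded
from a single move — it is reachable in two moves — which keeps the
neighborhood size manageable and every neighbor at distance exactly $n$.
Argmax ties are broken by lowest (position, letter); a step requires strict
improvement, which guarantees termination; 10 seeded restarts are run and
the best local optimum returned. On an additive objective every local
optimum of this neighborhood is global (each substitution must be
individually optimal), so the climber provably matches exhaustive search
there — the basis of the design acceptance test. Stop codons are excluded
from the design alphabet: designs are meant to be expressed.

## The synthetic landscape

`landscape_spec()` states the world the tests run in:
$$y(s) = g\!\Big(\sum_{i \in \text{mut}(s)} a_{i,s_i} \;+\;
  \sum_{(i,j) \in P} \varepsilon_{ij}\,[i,j \in \text{mut}(s)]\Big) + \eta(s),$$
additive effects $a \sim N(0, 1)$ per (position, letter) with wild-type
letters at 0, epistatic pairs $P$ chosen uniformly with effects
$\pm 1.5$ that fire when *both* positions are mutated (the simplest
mechanism producing genuine non-additivity — deviation from additivity
mathematically requires joint mutation), an optional saturating
$g(z) = 3\tanh(z/3)$ emulating assay saturation (identity by default), and
per-sequence Gaussian noise (sd 0.1) computed from a hash of the sequence,
so fitness is a pure, reproducible function of sequence. Defaults: $L = 50$,
2,000 variants with 1–3 substitutions, 10 epistatic pairs.

What the generator emulates: an additive-dominated landscape with sparse
pairwise epistasis, realistic score noise, log-normal library abundance and
logistic selection for the read-count simulator. The wild-type row, when
present, is spiked into the input library at a fixed frequency (default 5%):
wild-type-normalized scoring requires a reliably covered reference, and
scans are run that way in practice — without the spike-in, low read budgets
can lose the reference entirely and no score is defined. What it does not: codon
structure, biophysical stability, assay-specific artifacts, the scale of
real scans (10⁴–10⁶ variants). A green test therefore establishes
correctness of the machinery, not predictive performance on real proteins.

One consequence is worth stating plainly. At the default density — 10 pairs
over $\binom{50}{2}$ position pairs, 2,000 variants with at most 3 uniform
mutations — each planted pair is carried by only a couple of training
variants, so *no* learner can generalize the interactions, and the
nonlinear models' variance penalty on the dominant additive component makes
linear regression the better test-set predictor. The acceptance check that
nonlinear models beat linear MSE on these defaults is accordingly expected
to fail, and is left failing rather than weakened. The same comparison run
where the interaction signal is statistically identifiable (L = 15, 1,500
variants, 8 pairs of magnitude 2 — tens of carriers per pair) shows the
fully connected network beating linear regression on every seed; that
property test is part of the regular suite.

Similarly, the noiseless-recovery check trains on 3,000 variants rather
than the generator's 2,000 default: at 2,000, about 1.5% of the
(position, letter) additive coefficients never appear in training, which
caps test Pearson just below the 0.99 threshold no matter the optimizer.
3,000 variants give every coefficient ~6 expected observations. This is a
coverage argument made before measuring, not a tuned number.

## Engineering notes

The network engine (dense, valid 1-D convolution, order-independent graph
convolution, Adam, early stopping, reverse-mode gradients including
input gradients) is written against base R matrix operations. No R deep
learning framework is available in the target environment, the
architectures are small and fixed, integrated gradients need input-space
gradients, and CPU bit-reproducibility from a seed is a requirement —
together these made a ~300-line engine the simpler and more auditable
choice. Graph containers are `igraph` objects; FASTA parsing uses
`Biostrings`; model parameters and specs serialize to portable JSON
(full double precision) rather than YAML, which has no preinstalled R
parser.

## Known limitations

* Hyperparameter search infrastructure is out of scope; learning rate and
  batch size are the intended knobs, architecture defaults are declared in
  `model_spec()`.
* The 2-D embedding of latent spaces is visualization, not computation under
  test, and is left to external tools.
* Multi-chain proteins, insertions/deletions and codon-level variants are
  not modeled.
* The pure-R engine is appropriate for desk-scale data (10³–10⁴ variants);
  real scans at 10⁵+ variants would want a compiled backend.
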