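# dms2func

Supervised sequence–function models for deep mutational scanning (DMS) data,
in R.

A deep mutational scan screens a large library of protein variants through a
functional selection and sequences the pools before and after, giving each
variant a quantitative functional score. `dms2func` is for protein engineers
and computational biologists who want to learn the mapping
*f*(sequence) → score from such data and then use it: predict unseen
variants, rank candidates under a testing budget, ask which residues matter,
simulate how sequencing depth limits what can be learned, and design new
high-scoring sequences.

## What is inside

* **Variant handling** — substitution-string notation (`"E19Q,A24Y"`),
  validated datasets, TSV/FASTA I/O, Hamming distances.
* **Encoding** — per residue, a 21-letter one-hot block (20 amino acids +
  stop) concatenated with a *d*-dimensional PCA projection of an amino-acid
  property table (*d* = 19 captures 100% of the variance of any 20-row
  table). A synthetic property table ships in `inst/extdata/`.
* **Four regression architectures** — linear, fully connected, sequence
  convolutional (valid, no padding) and a graph convolutional network on a
  residue contact graph, using the order-independent operator

  z_i = σ( W_C·x_i + (1/|N_i|) Σ_{j∈N_i} W_N·x_j + b )

  with a center weight matrix W_C and a single weight matrix W_N shared by
  all neighbors. Contact graphs come from β-carbon distances under a 4–10 Å
  threshold; shuffled / disconnected / sequential / complete baseline graphs
  are included. Training is Adam + MSE with early stopping (patience 15,
  min delta 1e-5, max 300 epochs, best-epoch restore).
* **Experiments** — random 81/9/10 splits, mutational and positional
  extrapolation splits with provably disjoint train/test information,
  reduced-training-size replicates, correlation/MSE metrics, recall at
  budget, top-N statistics and a 1,000-ranking random baseline.
* **Resampling simulator** — wild-type-normalized log-ratio enrichment
  scores from read counts, multinomial resampling over a library-size ×
  read-budget grid, retraining per cell: the library-size vs. sequencing-
  depth trade-off.
* **Interpretation** — integrated gradients against the wild-type baseline
  (midpoint rule), per-position attribution profiles, latent
  representations, and the complete L × 21 single-mutant prediction matrix.
* **Design** — random-restart hill climbing over sequences at a fixed
  Hamming distance *n* from the wild type, maximizing the minimum predicted
  score over a model ensemble.
* **Synthetic landscapes** — seeded additive + pairwise-epistatic fitness
  generator with paired read-count simulation, so everything is testable
  without downloads.

See `vignettes/sequence-function-models.Rmd` for the model details and the
reasoning behind the numerical choices.

## Worked example

```r
library(dms2func)

# property projection from the packaged (synthetic) amino-acid table
props <- read_property_matrix(system.file("extdata",
          "aa_properties_synthetic.csv", package = "dms2func"))
proj <- fit_property_projection(props, d = 19)

# a seeded synthetic landscape stands in for a real scan
spec <- landscape_spec(L = 30, seed = 42)
ds <- sample_dataset(spec, n_variants = 800, seed = 43)
ds
#> <dms_dataset> synthetic: 800 variants (L = 30)

sp <- split_random(ds, seed = 1)
sp
#> <split_spec> random: 648 train / 72 tune / 80 test (0 discarded)

X <- encode_variants(ds, spec$wild_type, proj)
m <- build_model(model_spec("linear", seed = 1), spec$L, dim(X)[3])
m <- train_model(m, X[sp$train, , ], ds$data$score[sp$train],
                 X[sp$tune, , ],  ds$data$score[sp$tune],
                 training_config(lr = 0.02, batch_size = 64))

evaluate_model(m, X[sp$test, , ], ds$data$score[sp$test])
#> <eval_report> n = 80, Pearson 0.8836, Spearman 0.8795, MSE 0.54603

# with a testing budget of 20, how many of the 20 truly best test variants
# does the model's ranking recover?
recall_at_budget(predict(m, X[sp$test, , ]), ds$data$score[sp$test],
                 budget = 20, top_k = 20)
#> [1] 0.7

# design a triple mutant maximizing the (here single-model) ensemble minimum
hill_climb(list(m), spec$wild_type, proj, n = 3, restarts = 5, seed = 7)
#> <design_result> n = 3, objective 7.5424 (restart 1)
#> T1Q,E18F,I30E
```

The evaluation report reads as usual: Pearson/Spearman correlate predicted
with true scores on held-out variants; the recall value says 70% of the
truly best variants would be found within that budget; the design result is
a local optimum of the min-ensemble objective at exactly the requested
mutation distance.

## Command line

A thin CLI ships in `exec/`:

```sh
Rscript -e 'dms2func::dms2func_cli()' data validate --dataset d.tsv --wt wt.fasta
Rscript -e 'dms2func::dms2func_cli()' graph --pdb 2qmt.pdb --chain A --threshold 7 --out edges.txt
Rscript -e 'dms2func::dms2func_cli()' synth --seed 7 --out fixtures/
```

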