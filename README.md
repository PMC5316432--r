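# anfiscall

Per-base **confidence estimation for DNA base calling** with a hierarchical
adaptive neuro-fuzzy inference system (ANFIS), for people working with
Sanger-style sequencing traces who want a learned, interpretable quality
score per called base.

## The model

Each called base is described by six normalized trace features in [0,1]:
peakness of the called and runner-up peaks (`NP_called`, `NP_2nd`), their
heights (`NH_called`, `NH_2nd`) and the spacing to the neighboring peaks
(`dNS_next`, `dNS_prev`). Three two-input zero-order Sugeno systems score
the three feature groups,

    NC_P  = f(NP_called, NP_2nd)        (peakness,  triangular MFs)
    NC_H  = f(NH_called, NH_2nd)        (height,    two-sided Gaussian MFs)
    NC_dS = f(dNS_next,  dNS_prev)      (spacing,   trapezoidal MFs)

and a three-input main system (two-sided Gaussian MFs) maps the scores to
the confidence value `NC_o` in [0,1]. Every system uses 5 membership
functions per input on a full grid partition (25 rules per subsystem, 125
in the main system) with constant rule consequents; inference is the
firing-strength-weighted average

    y(x) = sum_i w_i(x) c_i / sum_i w_i(x),   w_i = prod_v mu_iv(x_v).

All parameters are trained by full-batch backpropagation (500 epochs,
adaptive step size; an exact least-squares/gradient hybrid is available)
on four files of 500 labeled samples, split 350/150 into train/test. The
original training files are unpublished, so the package ships a synthetic
generator that emulates their structure and supervises with fixed monotone
reference functions; see the methods vignette
(`vignettes/confidence-model.Rmd`) for what that does and does not
establish.

## Worked example

```r
library(anfiscall)
files <- make_training_files(generator_config(seed = 1))   # four 500-row files
model <- fit_pipeline(files, training_config(epochs = 500, seed = 1))
run_demo(model = model)
```

which prints (the right-hand block are the reference values of the
previously trained system the package emulates; agreement is expected in
*ordering*, not value — the training data behind the reference numbers was
never published):

```
Six-base example (ATCTCG): computed vs reference
base    NC_P    NC_H   NC_dS    NC_o |    refP    refH   refdS  refNCo
A      0.916   0.722   0.991   0.808 |   0.824   0.683   0.813   0.653
T      0.859   0.885   0.991   0.865 |   0.825   0.767   0.813   0.747
C      0.457   0.504   0.991   0.472 |   0.499   0.230   0.813   0.205
T      0.689   0.745   0.991   0.699 |   0.499   0.692   0.812   0.661
C      0.683   0.577   0.991   0.614 |   0.612   0.390   0.813   0.364
G      0.768   0.821   0.982   0.789 |   0.766   0.741   0.813   0.716
```

The third base — a weak C whose runner-up peak out-peaks the called one
(0.838 vs 0.794) — gets the lowest confidence in both columns. The fitted
model reports held-out RMSE against its synthetic targets in
`model$provenance` (0.0014–0.014 for the four systems in this run).

## Command line

```sh
Rscript -e 'quit(status = anfiscall::run_cli())' generate --out-dir data --seed 7
Rscript -e 'quit(status = anfiscall::run_cli())' train --data-dir data --out model.json --seed 7
Rscript -e 'quit(status = anfiscall::run_cli())' predict --model model.json --input data/records.csv --out results.csv
Rscript -e 'quit(status = anfiscall::run_cli())' eval --model model.json --system peakness --file data/peakness.csv
Rscript -e 'quit(status = anfiscall::run_cli())' demo --model model.json
```

Exit codes: 0 success, 2 validation error, 3 numeric failure. Flags
`--epochs`, `--method {backprop,hybrid}`, `--split {contiguous,shuffled}`,
`--seed`, `--n-train` override defaults; `--config file` reads `key = value`
lines.

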