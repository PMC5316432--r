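RECORD_COLUMNS <- c("base", "NP_called", "NP_2nd", "NH_called", "NH_2nd",
                    "dNS_next", "dNS_prev")

#' Confidence pipeline model
#'
#' The hierarchical architecture: three two-input feature subsystems whose
#' scores feed a three-input main system. Membership families are fixed per
#' system -- triangular for peakness, two-sided Gaussian for height,
#' trapezoidal for spacing, two-sided Gaussian for the main confidence
#' system -- with 5 MFs per input on `[0, 1]` throughout.
#'
#' `new_pipeline_model()` builds the untrained architecture; scoring an
#' untrained model raises a not-fitted error. Use [fit_pipeline()] to train.
#'
#' @param n_mfs membership functions per input (default 5).
#' @return an object of class `pipeline_model` with fields `peakness_fis`,
#'   `height_fis`, `spacing_fis`, `confidence_fis`, `fitted`, `provenance`.
#' @export
new_pipeline_model <- function(n_mfs = 5L) {
  two <- function(nm1, nm2, family)
    grid_partition(list(fuzzy_variable(nm1, n_mfs = n_mfs, family = family),
                        fuzzy_variable(nm2, n_mfs = n_mfs, family = family)))
  main <- grid_partition(list(
    fuzzy_variable("NC_P", n_mfs = n_mfs, family = "gauss2"),
    fuzzy_variable("NC_H", n_mfs = n_mfs, family = "gauss2"),
    fuzzy_variable("NC_dS", n_mfs = n_mfs, family = "gauss2")))
  structure(list(
    peakness_fis = two("NP_called", "NP_2nd", "triangular"),
    height_fis = two("NH_called", "NH_2nd", "gauss2"),
    spacing_fis = two("dNS_next", "dNS_prev", "trapezoidal"),
    confidence_fis = main,
    fitted = FALSE,
    provenance = NULL), class = "pipeline_model")
}

check_fitted <- function(model) {
  stopifnot(inherits(model, "pipeline_model"))
  if (!isTRUE(model$fitted))
    stop(errorCondition("pipeline model is not fitted; run fit_pipeline() first",
                        class = c("anfiscall_not_fitted",
                                  "anfiscall_validation_error", "anfiscall_error")))
}

#' Feature and confidence scores
#'
#' Apply one trained subsystem (or the main system) to feature values.
#' All are vectorized; inputs outside `[0, 1]` are clipped with a warning.
#'
#' @param model a fitted [new_pipeline_model()].
#' @param np_called,np_2nd normalized peakness of the called / runner-up peak.
#' @param nh_called,nh_2nd normalized height of the called / runner-up peak.
#' @param dns_next,dns_prev normalized spacing to the next / previous peak.
#' @param features for [score_confidence()]: a length-3 vector
#'   `(NC_P, NC_H, NC_dS)` or a 3-column matrix/data frame of feature scores.
#' @return numeric score(s) in `[0, 1]`.
#' @export
score_peakness <- function(model, np_called, np_2nd) {
  check_fitted(model)
  infer(model$peakness_fis, cbind(np_called, np_2nd))
}

#' @rdname score_peakness
#' @export
score_height <- function(model, nh_called, nh_2nd) {
  check_fitted(model)
  infer(model$height_fis, cbind(nh_called, nh_2nd))
}

#' @rdname score_peakness
#' @export
score_spacing <- function(model, dns_next, dns_prev) {
  check_fitted(model)
  infer(model$spacing_fis, cbind(dns_next, dns_prev))
}

#' @rdname score_peakness
#' @export
score_confidence <- function(model, features) {
  check_fitted(model)
  infer(model$confidence_fis, features)
}

# Validate a base-call record data frame; errors name the offending row.
validate_records <- function(records) {
  if (!is.data.frame(records))
    abort_validation("records must be a data frame")
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing))
    abort_validation("records are missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(records) == 0L) return(records[RECORD_COLUMNS])
  bad_base <- which(!records$base %in% c("A", "C", "G", "T"))
  if (length(bad_base))
    abort_validation("row %d: base must be one of A/C/G/T, got '%s'",
                     bad_base[1], records$base[bad_base[1]])
  feat <- as.matrix(records[RECORD_COLUMNS[-1]])
  if (!is.numeric(feat)) abort_validation("feature columns must be numeric")
  bad <- which(!is.finite(feat), arr.ind = TRUE)
  if (nrow(bad))
    abort_validation("row %d: non-finite value in column %s",
                     bad[1, 1], RECORD_COLUMNS[-1][bad[1, 2]])
  out <- which(feat < 0 | feat > 1, arr.ind = TRUE)
  if (nrow(out)) {
    warn_anfiscall("%d feature value(s) outside [0,1] were clipped (first at row %d)",
                   nrow(out), out[1, 1])
    records[RECORD_COLUMNS[-1]] <- clip01(feat)
  }
  records[RECORD_COLUMNS]
}

#' Score a sequence of called bases
#'
#' Runs the full cascade on each record: the three feature subsystems score
#' peakness, height and spacing from the six trace features, then the main
#' system turns the three scores into a per-base confidence value. Records
#' are independent; output order matches input order.
#'
#' @param model a fitted [new_pipeline_model()].
#' @param records data frame with columns `base`, `NP_called`, `NP_2nd`,
#'   `NH_called`, `NH_2nd`, `dNS_next`, `dNS_prev`.
#' @return data frame with columns `base`, `NC_P`, `NC_H`, `NC_dS`, `NC_o`.
#' @export
call_sequence <- function(model, records) {
  check_fitted(model)
  records <- validate_records(records)
  if (nrow(records) == 0L)
    return(data.frame(base = character(), NC_P = numeric(), NC_H = numeric(),
                      NC_dS = numeric(), NC_o = numeric(), stringsAsFactors = FALSE))
  nc_p <- score_peakness(model, records$NP_called, records$NP_2nd)
  nc_h <- score_height(model, records$NH_called, records$NH_2nd)
  nc_ds <- score_spacing(model, records$dNS_next, records$dNS_prev)
  nc_o <- score_confidence(model, cbind(NC_P = nc_p, NC_H = nc_h, NC_dS = nc_ds))
  data.frame(base = records$base, NC_P = nc_p, NC_H = nc_h, NC_dS = nc_ds,
             NC_o = nc_o, stringsAsFactors = FALSE)
}

#' Train the full pipeline
#'
#' Trains the three feature subsystems and the main confidence system from
#' four supervised files (two input columns each for peakness, height and
#' spacing; three for confidence). Each file is split into train/test parts
#' (350/150 by default for 500-record files), consequents start at the
#' midpoint of the file's observed target range and stay projected into
#' `[0, 1]` during training, which bounds every pipeline output to `[0, 1]`.
#'
#' @param files named list of four [sample_set()]s: `peakness`, `height`,
#'   `spacing`, `confidence` (the order of [make_training_files()]).
#' @param cfg a [training_config()] applied to all four systems.
#' @param n_train training records per file (default 350).
#' @param split_mode `"contiguous"` (default) or `"shuffled"`.
#' @param verbose per-epoch logging interval, 0 = silent.
#' @return a fitted `pipeline_model`; `$provenance` records the config, the
#'   split and the per-system final train/test RMSE.
#' @export
fit_pipeline <- function(files, cfg = training_config(), n_train = 350L,
                         split_mode = c("contiguous", "shuffled"), verbose = 0L) {
  split_mode <- match.arg(split_mode)
  expected <- c(peakness = 2L, height = 2L, spacing = 2L, confidence = 3L)
  if (!is.list(files) || !all(names(expected) %in% names(files)))
    abort_validation("files must be a named list with elements %s",
                     paste(names(expected), collapse = ", "))
  for (nm in names(expected)) {
    f <- files[[nm]]
    if (!inherits(f, "sample_set"))
      abort_validation("file '%s' is not a sample_set", nm)
    if (ncol(f$x) != expected[[nm]])
      abort_validation("file '%s' must have %d input column(s), has %d",
                       nm, expected[[nm]], ncol(f$x))
  }
  if (is.null(cfg$consequent_bounds)) cfg$consequent_bounds <- c(0, 1)

  model <- new_pipeline_model()
  slot_of <- c(peakness = "peakness_fis", height = "height_fis",
               spacing = "spacing_fis", confidence = "confidence_fis")
  prov <- list(config = unclass(cfg), n_train = n_train, split_mode = split_mode,
               systems = list())
  for (nm in names(expected)) {
    parts <- split_samples(files[[nm]], n_train = n_train, mode = split_mode,
                           seed = derive_seed(cfg$seed, match(nm, names(expected))))
    fis <- model[[slot_of[[nm]]]]
    rng <- range(parts$train$y)
    fis$consequents <- rep(mean(rng), length(fis$consequents))
    run <- anfis_train(fis, parts$train, cfg, test_set = parts$test,
                       verbose = verbose)
    model[[slot_of[[nm]]]] <- run$fis
    prov$systems[[nm]] <- list(
      final_train_rmse = run$train_rmse_by_epoch[cfg$epochs],
      test_rmse = run$test_rmse,
      initial_rmse = run$initial_rmse)
  }
  model$fitted <- TRUE
  model$provenance <- prov
  model
}

#' @export
print.pipeline_model <- function(x, ...) {
  cat(sprintf("<pipeline_model> %s\n",
              if (x$fitted) "fitted" else "untrained"))
  if (x$fitted && !is.null(x$provenance)) {
    for (nm in names(x$provenance$systems)) {
      s <- x$provenance$systems[[nm]]
      cat(sprintf("  %-10s train RMSE %.4f  test RMSE %.4f\n",
                  nm, s$final_train_rmse, s$test_rmse))
    }
  }
  invisible(x)
}

#' Read and write pipeline models
#'
#' A model bundle is a single JSON document holding the four serialized
#' systems plus the provenance block, written at full double precision so
#' round trips preserve every inference output exactly.
#'
#' @param model a `pipeline_model`.
#' @param path file path of the bundle.
#' @return `write_pipeline_model()` returns `path` invisibly;
#'   `read_pipeline_model()` the restored model.
#' @export
write_pipeline_model <- function(model, path) {
  stopifnot(inherits(model, "pipeline_model"))
  obj <- list(format = "anfiscall_pipeline_model", version = 1L,
              fitted = isTRUE(model$fitted),
              peakness_fis = fis_to_list(model$peakness_fis),
              height_fis = fis_to_list(model$height_fis),
              spacing_fis = fis_to_list(model$spacing_fis),
              confidence_fis = fis_to_list(model$confidence_fis),
              provenance = model$provenance)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, null = "null"),
             path)
  invisible(path)
}

#' @rdname write_pipeline_model
#' @export
read_pipeline_model <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "anfiscall_pipeline_model"))
    abort_validation("%s is not a pipeline model bundle", path)
  structure(list(
    peakness_fis = fis_from_list(obj$peakness_fis),
    height_fis = fis_from_list(obj$height_fis),
    spacing_fis = fis_from_list(obj$spacing_fis),
    confidence_fis = fis_from_list(obj$confidence_fis),
    fitted = isTRUE(obj$fitted),
    provenance = obj$provenance), class = "pipeline_model")
}

#' Six-base worked example
#'
#' `demo_records()` returns the bundled six-base example (sequence ATCTCG):
#' the six normalized trace features for each called base. `demo_reference()`
#' returns the feature scores and confidence values that a previously
#' trained reference system produced for the same bases; they are anchors
#' for qualitative comparison -- a model trained on synthetic data is not
#' expected to reproduce them numerically, but should reproduce their
#' ordering (the third base, a weak C with a runner-up peak stronger than
#' the called one, scores lowest).
#'
#' @return a data frame (six rows).
#' @export
demo_records <- function() {
  data.frame(
    base = c("A", "T", "C", "T", "C", "G"),
    NP_called = c(0.998, 0.999, 0.794, 0.999, 0.930, 0.999),
    NP_2nd    = c(0.361, 0.478, 0.838, 0.721, 0.665, 0.618),
    NH_called = c(0.889, 0.991, 0.644, 0.954, 0.696, 0.952),
    NH_2nd    = c(0.560, 0.421, 0.604, 0.606, 0.531, 0.485),
    dNS_next  = c(0.305, 0.305, 0.281, 0.286, 0.302, 0.274),
    dNS_prev  = c(0.298, 0.305, 0.305, 0.281, 0.286, 0.302),
    stringsAsFactors = FALSE)
}

#' @rdname demo_records
#' @export
demo_reference <- function() {
  data.frame(
    base  = c("A", "T", "C", "T", "C", "G"),
    NC_P  = c(0.824, 0.825, 0.499, 0.499, 0.612, 0.766),
    NC_H  = c(0.683, 0.767, 0.230, 0.692, 0.390, 0.741),
    NC_dS = c(0.813, 0.813, 0.813, 0.812, 0.813, 0.813),
    NC_o  = c(0.653, 0.747, 0.205, 0.661, 0.364, 0.716),
    stringsAsFactors = FALSE)
}

#' Run the six-base demo
#'
#' Trains a pipeline on default synthetic files (unless a fitted model is
#' supplied), scores the bundled six-base example and prints the computed
#' feature scores and confidence values side by side with the reference
#' values.
#'
#' @param model optional fitted `pipeline_model`; trained from scratch when
#'   `NULL`.
#' @param seed seed for synthetic training data when training from scratch.
#' @param epochs training epochs when training from scratch (default 500).
#' @param quiet suppress the printed report.
#' @return invisibly, a data frame with computed (`NC_*`) and reference
#'   (`ref_*`) columns.
#' @export
run_demo <- function(model = NULL, seed = 1L, epochs = 500L, quiet = FALSE) {
  if (is.null(model)) {
    if (!quiet) message(sprintf("training pipeline on synthetic data (seed %d, %d epochs) ...",
                                seed, epochs))
    files <- make_training_files(generator_config(seed = seed))
    model <- fit_pipeline(files, training_config(epochs = epochs, seed = seed))
  }
  res <- call_sequence(model, demo_records())
  ref <- demo_reference()
  out <- data.frame(base = res$base,
                    NC_P = res$NC_P, NC_H = res$NC_H, NC_dS = res$NC_dS,
                    NC_o = res$NC_o,
                    ref_NC_P = ref$NC_P, ref_NC_H = ref$NC_H,
                    ref_NC_dS = ref$NC_dS, ref_NC_o = ref$NC_o,
                    stringsAsFactors = FALSE)
  if (!quiet) {
    cat("Six-base example (ATCTCG): computed vs reference\n")
    fmt <- function(x) formatC(x, digits = 3, format = "f")
    hdr <- sprintf("%-4s %7s %7s %7s %7s | %7s %7s %7s %7s",
                   "base", "NC_P", "NC_H", "NC_dS", "NC_o",
                   "refP", "refH", "refdS", "refNCo")
    cat(hdr, "\n")
    for (i in seq_len(nrow(out)))
      cat(sprintf("%-4s %7s %7s %7s %7s | %7s %7s %7s %7s\n",
                  out$base[i], fmt(out$NC_P[i]), fmt(out$NC_H[i]),
                  fmt(out$NC_dS[i]), fmt(out$NC_o[i]),
                  fmt(out$ref_NC_P[i]), fmt(out$ref_NC_H[i]),
                  fmt(out$ref_NC_dS[i]), fmt(out$ref_NC_o[i])))
  }
  invisible(out)
}
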