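#' Synthetic trace-feature generator
#'
#' Configuration for simulating per-base chromatogram trace features. The
#' generator emulates 500-record sample files of six normalized features per
#' called base: peakness of the called and runner-up peaks (`NP_called`,
#' `NP_2nd`), their heights (`NH_called`, `NH_2nd`) and the normalized
#' spacing to the next/previous peak (`dNS_next`, `dNS_prev`), all in
#' `[0, 1]`.
#'
#' Records come from a two-population mixture. "Clean" bases have a
#' well-formed called peak (`NP_called` near 1, runner-up signal low) and
#' near-nominal spacing; "problem" bases have elevated runner-up features
#' (the competing peak can even beat the called one) and perturbed spacing.
#' Spreads scale with `noise_sd`, so `noise_sd = 0` collapses each
#' population onto its exemplar (clean `NP_called` exactly 1).
#'
#' @param n_records number of records (default 500, the sample-file size).
#' @param seed RNG seed; all draws are reproducible from it.
#' @param clean_fraction fraction of clean bases (default 0.7).
#' @param noise_sd feature jitter scale (default 0.03).
#' @param nominal_spacing center of the normalized spacing distribution
#'   (default 0.3; clean reads have near-uniform peak spacing there).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_records = 500L, seed = 1L, clean_fraction = 0.7,
                             noise_sd = 0.03, nominal_spacing = 0.3) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 10L)
    abort_validation("n_records must be >= 10")
  if (!is.numeric(clean_fraction) || clean_fraction < 0 || clean_fraction > 1)
    abort_validation("clean_fraction must lie in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_validation("noise_sd must be non-negative")
  if (!is.numeric(nominal_spacing) || nominal_spacing <= 0 || nominal_spacing >= 1)
    abort_validation("nominal_spacing must lie in (0, 1)")
  structure(list(n_records = n_records, seed = as.integer(seed),
                 clean_fraction = clean_fraction, noise_sd = noise_sd,
                 nominal_spacing = nominal_spacing),
            class = "generator_config")
}

# Population exemplars and unit spreads. `g` is the noise scale relative to
# the default noise_sd = 0.03; Beta draws give the one-sided pile-up of
# called-peak features just under 1 seen in clean traces.
GEN_CLEAN <- list(np2 = 0.40, nh2 = 0.50)
GEN_PROBLEM <- list(np1 = 0.80, np2 = 0.80, nh1 = 0.65, nh2 = 0.58)

#' Theoretical feature means of the generator
#'
#' Closed-form expectations of each feature under a [generator_config()],
#' ignoring the (negligible at default settings) truncation to `[0, 1]`.
#' Used by Monte-Carlo sanity tests.
#'
#' @param cfg a [generator_config()].
#' @return named numeric vector over the six features.
#' @export
generator_feature_means <- function(cfg) {
  g <- cfg$noise_sd / 0.03
  cf <- cfg$clean_fraction
  c(NP_called = cf * (1 - 0.15 * g * 2 / 7) + (1 - cf) * GEN_PROBLEM$np1,
    NP_2nd    = cf * GEN_CLEAN$np2 + (1 - cf) * GEN_PROBLEM$np2,
    NH_called = cf * (1 - 0.30 * g * 1.2 / 5.2) + (1 - cf) * GEN_PROBLEM$nh1,
    NH_2nd    = cf * GEN_CLEAN$nh2 + (1 - cf) * GEN_PROBLEM$nh2,
    dNS_next  = cfg$nominal_spacing,
    dNS_prev  = cfg$nominal_spacing)
}

#' Generate synthetic base-call records
#'
#' Simulates `cfg$n_records` consecutive called bases. Spacing is generated
#' as a single chain along the sequence so that `dNS_prev` of record `i`
#' equals `dNS_next` of record `i - 1` exactly, as it must for features
#' measured between adjacent peaks of one trace.
#'
#' @param cfg a [generator_config()].
#' @return a data frame with columns `base`, `NP_called`, `NP_2nd`,
#'   `NH_called`, `NH_2nd`, `dNS_next`, `dNS_prev`; all features in `[0, 1]`.
#' @export
generate_records <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_records
    g <- cfg$noise_sd / 0.03
    clean <- stats::runif(n) < cfg$clean_fraction

    np1 <- ifelse(clean,
                  1 - 0.15 * g * stats::rbeta(n, 2, 5),
                  GEN_PROBLEM$np1 + 3 * cfg$noise_sd * stats::rnorm(n))
    np2 <- ifelse(clean,
                  GEN_CLEAN$np2 + 3 * cfg$noise_sd * stats::rnorm(n),
                  GEN_PROBLEM$np2 + 3 * cfg$noise_sd * stats::rnorm(n))
    nh1 <- ifelse(clean,
                  1 - 0.30 * g * stats::rbeta(n, 1.2, 4),
                  GEN_PROBLEM$nh1 + 3 * cfg$noise_sd * stats::rnorm(n))
    nh2 <- ifelse(clean,
                  GEN_CLEAN$nh2 + 2 * cfg$noise_sd * stats::rnorm(n),
                  GEN_PROBLEM$nh2 + 2 * cfg$noise_sd * stats::rnorm(n))

    # spacing chain: n + 1 inter-peak gaps; gap i >= 1 belongs to record i,
    # gap 0 precedes the first record and inherits its population.
    owner_clean <- c(clean[1], clean)
    gap_sd <- ifelse(owner_clean, 0.02, 0.08) * g
    gaps <- cfg$nominal_spacing + gap_sd * stats::rnorm(n + 1)
    gaps <- clip01(gaps)

    data.frame(
      base = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      NP_called = clip01(np1),
      NP_2nd = clip01(np2),
      NH_called = clip01(nh1),
      NH_2nd = clip01(nh2),
      dNS_next = gaps[-1],
      dNS_prev = gaps[-(n + 1)],
      stringsAsFactors = FALSE)
  })
}

#' Monotone reference target functions
#'
#' Smooth supervising targets standing in for the unpublished training
#' labels of the original confidence model. `f_P` and `f_H` increase in the
#' called-peak feature and decrease in the runner-up feature; `f_S` is
#' symmetric in the two spacings and peaks when both sit at the nominal
#' spacing; `f_C` increases in every feature score. All map into `[0, 1]`.
#'
#' Closed forms:
#' \deqn{f_P(u, v) = u (1 - 0.6 v^2), \quad f_H \text{ analogous}}
#' \deqn{f_S(s, t) = \exp(-((s - s_0)^2 + (t - s_0)^2) / (2 \cdot 0.12^2))}
#' \deqn{f_C(p, h, s) = \sqrt{p h} (0.7 + 0.3 s)}
#'
#' @param nominal_spacing the spacing `s0` at which `f_S` is maximal.
#' @return a list of vectorized functions `f_P`, `f_H`, `f_S`, `f_C`.
#' @export
reference_functions <- function(nominal_spacing = 0.3) {
  s0 <- nominal_spacing
  list(
    f_P = function(np_called, np_2nd) clip01(np_called * (1 - 0.6 * np_2nd^2)),
    f_H = function(nh_called, nh_2nd) clip01(nh_called * (1 - 0.6 * nh_2nd^2)),
    f_S = function(dns_next, dns_prev)
      exp(-((dns_next - s0)^2 + (dns_prev - s0)^2) / (2 * 0.12^2)),
    f_C = function(nc_p, nc_h, nc_ds) sqrt(nc_p * nc_h) * (0.7 + 0.3 * nc_ds))
}

#' Build the four training files
#'
#' Produces the four supervised sample sets the pipeline trains on, each of
#' `cfg$n_records` rows: one two-input file per feature subsystem (peakness,
#' height, spacing) and one three-input file for the main confidence system
#' whose inputs are the reference feature scores. Each file draws its own
#' record batch from a sub-seed derived deterministically from `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @param ref reference functions, see [reference_functions()].
#' @return named list of four [sample_set()]s: `peakness`, `height`,
#'   `spacing`, `confidence`.
#' @export
make_training_files <- function(cfg, ref = reference_functions(cfg$nominal_spacing)) {
  stopifnot(inherits(cfg, "generator_config"))
  batch <- function(k) {
    sub <- cfg
    sub$seed <- derive_seed(cfg$seed, k)
    generate_records(sub)
  }
  r1 <- batch(1L); r2 <- batch(2L); r3 <- batch(3L); r4 <- batch(4L)
  list(
    peakness = sample_set(cbind(NP_called = r1$NP_called, NP_2nd = r1$NP_2nd),
                          ref$f_P(r1$NP_called, r1$NP_2nd), "peakness"),
    height = sample_set(cbind(NH_called = r2$NH_called, NH_2nd = r2$NH_2nd),
                        ref$f_H(r2$NH_called, r2$NH_2nd), "height"),
    spacing = sample_set(cbind(dNS_next = r3$dNS_next, dNS_prev = r3$dNS_prev),
                         ref$f_S(r3$dNS_next, r3$dNS_prev), "spacing"),
    confidence = {
      p <- ref$f_P(r4$NP_called, r4$NP_2nd)
      h <- ref$f_H(r4$NH_called, r4$NH_2nd)
      s <- ref$f_S(r4$dNS_next, r4$dNS_prev)
      sample_set(cbind(NC_P = p, NC_H = h, NC_dS = s),
                 ref$f_C(p, h, s), "confidence")
    })
}
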