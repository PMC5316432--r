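#' Fuzzy input variable
#'
#' A named input with a closed domain (default `[0, 1]`) carrying an ordered
#' list of membership functions. `fuzzy_variable()` builds the standard
#' grid-partition initialization: `n_mfs` centers uniformly spaced over the
#' domain, with family-specific shapes chosen so the whole domain is covered
#' (every point has at least one MF with positive degree):
#' triangular feet sit at the neighboring centers; trapezoidal shoulders at
#' center +/- spacing/4 with feet at neighboring centers; gauss2 plateaus of
#' half-width spacing/8 with sigma = spacing/2.5.
#'
#' @param name variable name.
#' @param domain length-2 numeric, closed interval (default `c(0, 1)`).
#' @param n_mfs number of membership functions (>= 2; default 5).
#' @param family MF family for every set on this variable.
#' @return an object of class `anfis_variable`.
#' @examples
#' v <- fuzzy_variable("NP_called", n_mfs = 5, family = "triangular")
#' sapply(v$mfs, function(m) m$params[2])  # apexes at 0, .25, .5, .75, 1
#' @export
fuzzy_variable <- function(name, domain = c(0, 1), n_mfs = 5L,
                           family = c("triangular", "trapezoidal", "gauss2")) {
  family <- match.arg(family)
  if (!is.numeric(domain) || length(domain) != 2L || domain[2] <= domain[1])
    abort_validation("domain must be an interval c(lo, hi) with lo < hi")
  n_mfs <- as.integer(n_mfs)
  if (is.na(n_mfs) || n_mfs < 2L)
    abort_validation("n_mfs must be an integer >= 2, got %s", format(n_mfs))
  lo <- domain[1]; hi <- domain[2]
  centers <- seq(lo, hi, length.out = n_mfs)
  h <- centers[2] - centers[1]
  clamp <- function(x) pmin(hi, pmax(lo, x))
  mfs <- lapply(seq_len(n_mfs), function(k) {
    ctr <- centers[k]
    params <- switch(family,
      triangular  = clamp(c(ctr - h, ctr, ctr + h)),
      trapezoidal = clamp(c(ctr - h, ctr - h / 4, ctr + h / 4, ctr + h)),
      gauss2      = c(h / 2.5, clamp(ctr - h / 8), h / 2.5, clamp(ctr + h / 8)))
    membership_function(family, params)
  })
  structure(list(name = as.character(name), domain = c(lo, hi), mfs = mfs),
            class = "anfis_variable")
}

# Low-level constructor used by deserialization: takes prebuilt MFs and
# checks the strictly-increasing-centers invariant.
new_fuzzy_variable <- function(name, domain, mfs) {
  if (length(mfs) < 2L) abort_validation("variable '%s' needs >= 2 MFs", name)
  ctrs <- vapply(mfs, mf_center, numeric(1))
  if (any(diff(ctrs) <= 0))
    abort_validation("MF centers of variable '%s' must be strictly increasing", name)
  structure(list(name = as.character(name), domain = as.numeric(domain), mfs = mfs),
            class = "anfis_variable")
}

# Degree matrix: length(x) points x n_mfs columns.
variable_degrees <- function(var, x) {
  deg <- vapply(var$mfs, mf_eval, numeric(length(x)), x = x)
  if (!is.matrix(deg)) deg <- matrix(deg, nrow = length(x))
  deg
}

#' Grid-partitioned zero-order Sugeno system
#'
#' Builds the full-factorial rule base over the given input variables: one
#' rule per combination of membership-function indices, each with a constant
#' consequent (zero-order Sugeno). With 2 inputs of 5 MFs this yields 25
#' rules; with 3 inputs, 125.
#'
#' @param variables list of [fuzzy_variable()] objects (>= 1).
#' @param tnorm conjunction operator for rule firing strengths: `"product"`
#'   (default, the ANFIS standard) or `"min"`.
#' @param consequent initial constant consequent for every rule (default 0.5,
#'   the midpoint of the unit output range).
#' @return an object of class `sugeno_fis` with fields `inputs`,
#'   `antecedents` (rule-by-input MF index matrix), `consequents`, `tnorm`.
#' @examples
#' fis <- grid_partition(list(
#'   fuzzy_variable("a", n_mfs = 5, family = "triangular"),
#'   fuzzy_variable("b", n_mfs = 5, family = "triangular")))
#' nrow(fis$antecedents)  # 25
#' @export
grid_partition <- function(variables, tnorm = c("product", "min"),
                           consequent = 0.5) {
  tnorm <- match.arg(tnorm)
  if (!is.list(variables) || length(variables) < 1L ||
      !all(vapply(variables, inherits, logical(1), "anfis_variable")))
    abort_validation("variables must be a non-empty list of fuzzy variables")
  counts <- vapply(variables, function(v) length(v$mfs), integer(1))
  ant <- as.matrix(expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE))
  dimnames(ant) <- list(NULL, vapply(variables, `[[`, character(1), "name"))
  structure(list(inputs = variables,
                 antecedents = ant,
                 consequents = rep(as.numeric(consequent), nrow(ant)),
                 tnorm = tnorm),
            class = "sugeno_fis")
}

n_inputs <- function(fis) length(fis$inputs)

# Rule firing strengths for a sample matrix X (n x d): returns n x R matrix.
firing_strengths <- function(fis, X) {
  d <- n_inputs(fis)
  ant <- fis$antecedents
  W <- NULL
  for (v in seq_len(d)) {
    deg <- variable_degrees(fis$inputs[[v]], X[, v])
    Wv <- deg[, ant[, v], drop = FALSE]
    W <- if (is.null(W)) Wv
         else if (fis$tnorm == "product") W * Wv
         else pmin(W, Wv)
  }
  W
}

# Clip columns of X to each variable's domain, warning once if anything moved.
clip_to_domain <- function(fis, X) {
  moved <- FALSE
  for (v in seq_len(n_inputs(fis))) {
    dom <- fis$inputs[[v]]$domain
    col <- X[, v]
    cl <- pmin(dom[2], pmax(dom[1], col))
    if (any(cl != col)) moved <- TRUE
    X[, v] <- cl
  }
  if (moved)
    warn_anfiscall("inputs outside the variable domain were clipped")
  X
}

as_input_matrix <- function(fis, x) {
  d <- n_inputs(fis)
  if (is.matrix(x) || is.data.frame(x)) {
    X <- as.matrix(x)
  } else {
    x <- as.numeric(x)
    X <- matrix(x, ncol = d, byrow = TRUE)
  }
  if (ncol(X) != d)
    abort_validation("expected %d input column(s), got %d", d, ncol(X))
  if (any(!is.finite(X)))
    abort_validation("inputs must be finite")
  storage.mode(X) <- "double"
  X
}

#' Sugeno inference
#'
#' Zero-order Sugeno output: the firing-strength-weighted average of the
#' rule consequents, `sum(w_i * c_i) / sum(w_i)`. Bounded by the consequent
#' range. Inputs outside a variable's domain are clipped with a warning.
#' A total firing strength of exactly zero cannot occur for a freshly
#' grid-partitioned system (full coverage) but is guarded: the offending
#' sample gets an epsilon denominator and a warning.
#'
#' @param fis a `sugeno_fis`.
#' @param x a single sample (numeric vector of length `n` inputs) or an
#'   `n_samples x n_inputs` matrix/data frame.
#' @return numeric vector of outputs, one per sample.
#' @export
infer <- function(fis, x) {
  stopifnot(inherits(fis, "sugeno_fis"))
  X <- clip_to_domain(fis, as_input_matrix(fis, x))
  W <- firing_strengths(fis, X)
  S <- rowSums(W)
  dead <- S == 0
  if (any(dead)) {
    warn_anfiscall("zero total firing strength for %d sample(s); using epsilon denominator",
                   sum(dead))
    S[dead] <- 1e-12
  }
  as.numeric(W %*% fis$consequents) / S
}

#' @export
print.sugeno_fis <- function(x, ...) {
  fams <- vapply(x$inputs, function(v) v$mfs[[1]]$family, character(1))
  cat(sprintf("<sugeno_fis> %d input(s) [%s], %d rules, tnorm = %s\n",
              n_inputs(x),
              paste(sprintf("%s:%s x%d", vapply(x$inputs, `[[`, character(1), "name"),
                            fams, vapply(x$inputs, function(v) length(v$mfs), integer(1))),
                    collapse = ", "),
              nrow(x$antecedents), x$tnorm))
  invisible(x)
}

# ---- JSON serialization ----------------------------------------------------

fis_to_list <- function(fis) {
  list(
    inputs = lapply(fis$inputs, function(v) list(
      name = v$name,
      domain = v$domain,
      mfs = lapply(v$mfs, function(m) list(family = m$family, params = m$params)))),
    rules = lapply(seq_len(nrow(fis$antecedents)), function(i) list(
      antecedent = as.integer(fis$antecedents[i, ]),
      consequent = fis$consequents[i])),
    tnorm = fis$tnorm)
}

fis_from_list <- function(obj) {
  vars <- lapply(obj$inputs, function(v) {
    mfs <- lapply(v$mfs, function(m)
      membership_function(m$family, as.numeric(unlist(m$params))))
    new_fuzzy_variable(v$name, as.numeric(unlist(v$domain)), mfs)
  })
  ant <- do.call(rbind, lapply(obj$rules, function(r) as.integer(unlist(r$antecedent))))
  cons <- vapply(obj$rules, function(r) as.numeric(r$consequent), numeric(1))
  if (ncol(ant) != length(vars))
    abort_validation("rule antecedent length does not match input count")
  dimnames(ant) <- list(NULL, vapply(vars, `[[`, character(1), "name"))
  structure(list(inputs = vars, antecedents = ant, consequents = cons,
                 tnorm = match.arg(obj$tnorm, c("product", "min"))),
            class = "sugeno_fis")
}

#' Read and write Sugeno systems as JSON
#'
#' Numbers are written with 17 significant digits, enough to reconstruct
#' every IEEE double exactly, so a write/read round trip is bit-faithful
#' for every parameter.
#'
#' @param fis a `sugeno_fis`.
#' @param path file path.
#' @return `write_fis()` returns `path` invisibly; `read_fis()` a `sugeno_fis`.
#' @export
write_fis <- function(fis, path) {
  stopifnot(inherits(fis, "sugeno_fis"))
  json <- jsonlite::toJSON(fis_to_list(fis), auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_fis
#' @export
read_fis <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: %s", path)
  fis_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}
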