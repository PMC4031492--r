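#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats cor pnorm pt sd var
NULL

# Classed conditions so callers can distinguish contract violations from
# schema/calibration problems programmatically.
stop_contract <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("signalpls_contract_error", "signalpls_error"))
}

stop_schema <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("signalpls_schema_error", "signalpls_error"))
}

stop_calibration <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("signalpls_calibration_error", "signalpls_error"))
}

stop_selection <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("signalpls_selection_error", "signalpls_error"))
}

#' Derive a per-stage random seed from one global seed
#'
#' One user-facing seed is expanded into independent substreams so that, for
#' example, changing the number of permutations never perturbs the synthetic
#' dataset generated from the same seed.
#'
#' @param seed Integer global seed.
#' @param stage Stage name, e.g. `"synthesis"` or `"permutation"`.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stage) == 1)
  offset <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) + offset * 7919) %% 2147483587)
}

# Column-wise standard deviation with a configurable divisor convention.
col_sds <- function(X, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  s <- apply(X, 2, stats::sd)
  if (sd_type == "population") {
    n <- nrow(X)
    s <- s * sqrt((n - 1) / n)
  }
  s
}

vec_sd <- function(y, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  s <- stats::sd(y)
  if (sd_type == "population") s <- s * sqrt((length(y) - 1) / length(y))
  s
}
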