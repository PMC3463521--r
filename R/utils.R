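# internal helpers shared across modules

# classed conditions: schema errors cover malformed files/tables, model errors
# cover invalid parameters or impossible model input; the CLI maps them to
# exit codes 2 and 3 respectively
abort_schema <- function(message, ...) {
  abort(message, class = c("quadrivalent_schema_error", "quadrivalent_error"), ...)
}

abort_model <- function(message, ...) {
  abort(message, class = c("quadrivalent_model_error", "quadrivalent_error"), ...)
}

# probability vectors must sit on the simplex to within this tolerance
SIMPLEX_TOL <- 1e-9

check_simplex <- function(p, what = "probabilities", tol = SIMPLEX_TOL) {
  if (any(!is.finite(p)) || any(p < -tol)) {
    abort_model(sprintf("%s must be finite and non-negative", what))
  }
  if (abs(sum(p) - 1) > tol) {
    abort_model(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
  }
  invisible(p)
}

# commercial ("half-up") rounding, matching how the printed frequency tables
# were rounded; base round() goes half-to-even
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# lower-truncated normal draws via inverse-CDF so that a fixed seed gives
# identical output regardless of how many draws would have been rejected
rtruncnorm_lower <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- pnorm((lower - mean[pos]) / sd[pos])
    u <- runif(sum(pos), min = plo, max = 1)
    out[pos] <- mean[pos] + sd[pos] * qnorm(pmin(u, 1 - 1e-16))
  }
  pmax(out, lower)
}

`%||%` <- rlang::`%||%`
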