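# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("twolibde_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("twolibde_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_count_vector <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop_input(name, " must be non-negative integers")
  invisible(x)
}

# Wilson score interval for a binomial proportion; used for empirical
# power/FPR cells where the normal interval misbehaves near 0 and 1.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # pin the degenerate endpoints: upper at p-hat = 1 (and lower at 0) equal
  # the estimate exactly, but the algebra above is off by one ulp
  c(lower = if (k == 0) 0 else max(0, centre - half),
    upper = if (k == n) 1 else min(1, centre + half))
}
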