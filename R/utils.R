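# Internal input-checking helpers. Error classes are stable so callers (and
# the CLI) can branch on them.

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_invalid("`{name}` must be a single finite number.", name = name)
  }
  invisible(x)
}

abort_invalid <- function(msg, ..., class = "lvrsim_error_invalid_input") {
  env <- list2env(list(...), parent = emptyenv())
  # poor-man's glue: substitute {name} tokens from ...
  for (nm in ls(env)) {
    msg <- gsub(paste0("{", nm, "}"), format(get(nm, envir = env)), msg, fixed = TRUE)
  }
  rlang::abort(msg, class = class)
}

# Apportion `total` into integer counts proportional to `weights`, summing to
# `total` exactly (largest-remainder rounding; ties broken by index order).
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (sum(weights) == 0) {
    if (total > 0) abort_invalid("cannot apportion a positive total over zero weights.")
    return(rep(0, length(weights)))
  }
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  short <- round(total - sum(base))
  if (short > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  base
}
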