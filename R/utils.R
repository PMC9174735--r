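# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Descriptive percentage tables round 0.5 up (e.g. 12.5 -> 13), unlike
#' [base::round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(12.5)  # 13, not 12
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# z-score that tolerates zero variance (returns 0s) and keeps attributes off
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

# stop() with a class so tests can target specific failure modes
abort <- function(msg, class) {
  stop(structure(class = c(class, "coalrank_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_date <- function(x, what) {
  if (!inherits(x, "Date")) {
    x2 <- tryCatch(as.Date(x), error = function(e) NULL)
    if (is.null(x2) || anyNA(x2) && !anyNA(x)) {
      abort(sprintf("'%s' must be a Date or ISO-8601 string", what),
            "coalrank_config_error")
    }
    return(x2)
  }
  x
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(miss, collapse = ", ")),
          "coalrank_data_error")
  }
  invisible(df)
}

# deterministic child seeds below 2^31, derived from a user seed + stream
# tag via a polynomial rolling hash (order-sensitive, collision-resistant)
child_seed <- function(seed, stream) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(stream)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}
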