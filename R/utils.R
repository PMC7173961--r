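# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                              allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && !is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# minmod slope limiter, vectorized
minmod <- function(a, b) {
  s <- (sign(a) + sign(b)) / 2
  s * pmin(abs(a), abs(b))
}

# volume-weighted mean
wmean <- function(x, w) sum(x * w) / sum(w)

# linear interpolation of the first downward crossing of `y` through `level`;
# returns NA if it never crosses
first_crossing_time <- function(t, y, level) {
  below <- which(y < level)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(t[1L])
  f <- (level - y[i - 1L]) / (y[i] - y[i - 1L])
  t[i - 1L] + f * (t[i] - t[i - 1L])
}

read_json_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
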