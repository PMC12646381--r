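# Internal validation and small shared helpers.

.stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

.assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) .stop_cfg(name, "must be TRUE or FALSE")
  invisible(x)
}

.assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) ||
      x < if (positive) 1 else 0) {
    .stop_cfg(name, if (positive) "must be a positive integer" else "must be a non-negative integer")
  }
  invisible(as.integer(x))
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    .stop_cfg(name, "must be a probability in [0, 1]")
  }
  invisible(as.numeric(x))
}

.assert_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    .stop_cfg(name, "must be a non-empty string")
  }
  invisible(x)
}

# days per prediction-window month count; 3 -> 91, 6 -> 182, aligned with the
# relative-time token boundaries
.window_days <- function(window_months) {
  if (!window_months %in% c(3L, 6L)) {
    stop("window_months must be 3 or 6", call. = FALSE)
  }
  if (window_months == 3L) 91L else 182L
}

.is_date <- function(x) inherits(x, "Date")

`%||%` <- function(a, b) if (is.null(a)) b else a
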