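#' @keywords internal
"_PACKAGE"

# Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# Shared guard for scalar numeric parameters.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must not be NULL", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(NULL)
}

# data.frame column check with a typed error message.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}
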