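#' @keywords internal
"_PACKAGE"

# Logging goes to stderr with a timestamp. Level is controlled by
# options(hypoxiaSig.log_level = "debug" | "info" | "warn" | "none").
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, none = 4L)

hx_log <- function(msg, level = "info") {
  threshold <- getOption("hypoxiaSig.log_level", "info")
  if (.log_levels[[level]] < .log_levels[[threshold]]) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), msg))
  invisible(NULL)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_input("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_input("`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max)
  if (!ok) stop_input("`%s` must be a finite number in the stated range", name)
  as.numeric(x)
}
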