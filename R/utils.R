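# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(structure(class = c("isomirpanel_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# seeds for internal stages are derived from the user seed; keep below 2^31
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_data("`", name, "` must be a single finite number")
  ok <- if (open) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop_data("`", name, "` = ", x, " is outside ",
              if (open) "(" else "[", lower, ", ", upper,
              if (open) ")" else "]")
  invisible(x)
}

# atomic write: stream to a temp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop_data("could not move temporary file onto ", path)
  invisible(path)
}
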