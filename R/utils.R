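# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rm <- function(...) stop(sprintf(...), call. = FALSE)

warn_rm <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_rm(...)
  invisible(TRUE)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed below 2^31, derived from a parent seed and a tag.
derive_seed <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(as.character(tag))) * 1009L) %% 2147483647L
}

# rbind a list of data.frames; NULL when empty
rbind_list <- function(rows) {
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x, open_low = TRUE, open_high = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_low) x > 0 else x >= 0) && (if (open_high) x < 1 else x <= 1)
}
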