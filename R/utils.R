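`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage- or task-specific random seed from a master seed
#'
#' Mixes a master seed with a character label so that independent pipeline
#' stages (or permutation tests for different tasks) consume independent,
#' reproducible random streams. The result is always a valid 32-bit integer
#' seed.
#'
#' @param seed Integer master seed, or `NULL` (returns `NULL`, meaning "do not
#'   reseed").
#' @param label Character scalar naming the stage/task.
#' @return An integer seed, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.character(label), length(label) == 1L)
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Run code under a temporary seed without permanently disturbing the caller's
# RNG state; seed = NULL uses the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

abort_ <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "tidegem_error")))
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort_("'%s' must be a single number in [%s, %s]", name, format(lo),
           format(hi), class = "tidegem_config_error")
  }
  invisible(x)
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
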