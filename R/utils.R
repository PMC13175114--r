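#' Numerically stable log-sum-exp
#'
#' @param x Numeric vector of log-scale values (`-Inf` allowed).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulators are pure functions of
#' their `seed` argument and never perturb the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based seed forking: stage reordering cannot silently change draws
# because each (base, stream, index) triple maps to a fixed child seed < 2^31.
fork_seed <- function(base, stream, index = 0L) {
  stopifnot(is.numeric(base), length(base) == 1L)
  as.integer((as.double(base) * 7919 + stream * 104729 + index * 131) %% 2147483647)
}

#' Package-level logging
#'
#' Filter drop counts and stage progress are emitted through [message()] at
#' or above the level set by `options(pqtlx.verbose = )` (0 = silent,
#' 1 = info, 2 = debug; default 1).
#'
#' @param fmt `sprintf` format string.
#' @param ... Values interpolated into `fmt`.
#' @param level Message level (1 = info, 2 = debug).
#' @keywords internal
pqtlx_log <- function(fmt, ..., level = 1L) {
  verb <- getOption("pqtlx.verbose", 1L)
  if (verb >= level) message(sprintf(paste0("[pqtlx] ", fmt), ...))
  invisible(NULL)
}

# Write a numeric-safe TSV: numerics rendered with %.17g so a write/read
# round trip is exact to well under 1e-12 relative.
write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
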