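#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific child seed from one master seed.
# All randomness in the package flows from a single integer seed; each named
# stream gets its own deterministic offset so adding a stage never perturbs
# the draws of another.  Result is kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) + 1000003 * h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_int <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_arg("`%s` must be a single integer >= %s", name, min)
  invisible(as.integer(x))
}

# canonical arc container: character matrix with columns from,to (0 rows ok)
as_arc_matrix <- function(arcs) {
  if (is.null(arcs)) return(matrix(character(), 0L, 2L,
                                   dimnames = list(NULL, c("from", "to"))))
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs[, 1:2])
  if (is.character(arcs) && is.null(dim(arcs)) && length(arcs) == 2L)
    arcs <- matrix(arcs, 1L, 2L)
  if (!is.matrix(arcs) || ncol(arcs) != 2L)
    stop_arg("arcs must be a two-column (from, to) matrix or data frame")
  storage.mode(arcs) <- "character"
  dimnames(arcs) <- list(NULL, c("from", "to"))
  arcs
}

arc_ids <- function(arcs) {
  arcs <- as_arc_matrix(arcs)
  paste(arcs[, 1L], arcs[, 2L], sep = "\r")
}
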