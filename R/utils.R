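# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# scalar count >= 0
check_count <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name = deparse(substitute(x)),
                           lo = 0, hi = 1, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a fraction in %s%g, %g%s", name,
                 if (strict) "(" else "[", lo, hi,
                 if (strict) ")" else "]"), call. = FALSE)
  }
  as.numeric(x)
}

# site keys used as dosage-matrix column names, sorted by (contig, position)
site_key <- function(contig, pos) paste0(contig, ":", pos)

site_order <- function(contig, pos) order(contig, pos)
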