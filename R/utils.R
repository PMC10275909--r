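#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic entry points take an explicit seed; nothing relies on
## ambient .Random.seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Content fingerprint used for provenance stamping: md5 of the
## serialized object (written to a scratch file; base R has no in-memory
## md5). Stable across runs for plain lists/vectors.
fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}

## Provenance block attached to results and written next to outputs.
## Deliberately timestamp-free so identical runs are byte-identical.
make_provenance <- function(params, inputs) {
  list(
    tool = "wcsea",
    version = as.character(utils::packageVersion("wcsea")),
    params = params,
    input_md5 = lapply(inputs, fingerprint)
  )
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

assert_gene_set <- function(x, what = "gene set") {
  if (!is.character(x) || length(x) == 0L || anyNA(x) || any(x == ""))
    stop2("%s must be a non-empty character vector without NA/empty entries",
          what)
  invisible(unique(x))
}
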