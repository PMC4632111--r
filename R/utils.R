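## internal helpers

formatPpm <- function(x) sprintf("%.3f", x)

## Coerce BinnedSpectra / matrix input to a plain numeric matrix D plus labels.
asDataMatrix <- function(D) {
  if (is(D, "BinnedSpectra")) {
    list(values = D@values, sampleIds = D@sampleIds, binCenters = D@binCenters)
  } else if (is.matrix(D) && is.numeric(D)) {
    sid <- rownames(D)
    if (is.null(sid)) sid <- paste0("s", seq_len(nrow(D)))
    bc <- suppressWarnings(as.numeric(colnames(D)))
    if (is.null(colnames(D)) || anyNA(bc)) bc <- as.numeric(seq_len(ncol(D)))
    list(values = unname(D), sampleIds = sid, binCenters = bc)
  } else {
    stop("'D' must be a BinnedSpectra object or a numeric matrix")
  }
}

## Deterministic child seeds derived from a master seed, kept below 2^31.
childSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 0)
  if (n == 0) return(integer())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## Run an expression with a local RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
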