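## internal helpers

## evaluate `code` under a given seed, restoring the caller's RNG state;
## with seed = NULL the code runs on the current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(eval.parent(substitute(code)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

## canonical string key for a support (sorted index set)
support_key <- function(w) {
  if (length(w) == 0L) return("")
  paste(sort(as.integer(w)), collapse = ",")
}

## order a list of supports by (size, lexicographic on sorted indices);
## used for deterministic tie-breaking in criterion minimization
support_order <- function(supports) {
  sizes <- vapply(supports, length, 1L)
  keys <- vapply(supports, function(w) {
    if (length(w) == 0L) return("")
    paste(sprintf("%06d", sort(as.integer(w))), collapse = ".")
  }, "")
  order(sizes, keys)
}
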