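# run expr under a fixed RNG seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Log2 ratio with symmetric pseudocount
#' @param num,den non-negative numerics.
#' @param pseudocount added to both.
#' @return log2((num + p) / (den + p)).
#' @export
log2_ratio <- function(num, den, pseudocount = 0.01) {
  log2((num + pseudocount) / (den + pseudocount))
}
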