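# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_values <- function(x) {
  if (inherits(x, "scr_ts") || inherits(x, "scr_epoch")) x$values
  else as.numeric(x)
}

rel_err <- function(est, truth) abs(est - truth) / pmax(abs(truth), .Machine$double.eps)

rel_l2 <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}
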