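## NULL default helper
`%||%` <- function(a, b) if (is.null(a)) b else a

## sample() without the scalar-x pitfall
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

abmapr_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[abmapr] ", ...)
}

## recursively drop S3 classes so nested configs serialize as plain lists
strip_classes <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, strip_classes) else x
}

## FNV-1a hash of a character scalar; used to stamp provenance on artifacts.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## Adam optimizer over a nested list of numeric arrays.
adam_init <- function(params) {
  zeros <- rapply(params, function(p) array(0, dim = dim(p) %||% length(p)),
                  how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      walk(p, g, m, v)
    }
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

## elementwise sum of two nested lists of arrays
grad_add <- function(a, b) {
  if (is.list(a)) Map(grad_add, a, b) else a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) lapply(a, grad_scale, s = s) else a * s
}

grad_zeros_like <- function(params) {
  rapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  }, how = "replace")
}
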