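# Shared numerical helpers: activations, initialisation, Adam, seed fan-out.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds by hashing the stage
#' name, so stages can be re-run in isolation and still reproduce their part
#' of a full run.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 1e6 * 10007 + h * 257) %% 2147483629)
}

# Glorot-uniform initial weights; callers set the RNG seed.
glorot <- function(fan_in, fan_out, shape = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(shape), -lim, lim), dim = shape)
}

# Minimal Adam optimiser over a named list of arrays. `state` holds first and
# second moments plus the step counter; `grads` must match `params` by name.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(dim(params[[nm]]))) g <- as.vector(g) else dim(g) <- dim(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moving average over trailing windows, used by loss-monotonicity checks.
smooth_windows <- function(x, width = 50L) {
  n <- length(x)
  if (n <= width) return(mean(x))
  starts <- seq(1L, n - width + 1L, by = width)
  vapply(starts, function(s) mean(x[s:min(s + width - 1L, n)]), numeric(1))
}

stop_proust <- function(...) stop(..., call. = FALSE)
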