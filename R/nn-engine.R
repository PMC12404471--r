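# Shared plumbing for the C++ compute core: parameter initialization over the
# flat weight vector, the Adam optimizer, and scoped seeding.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' stream afterwards. Every stochastic component of the package routes its
#' randomness through this helper, which is what makes simulated videos,
#' training runs and embeddings reproducible.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Glorot-uniform weights, zero biases, unit norm gains; the forget-gate block
# of each ConvLSTM bias starts at 1 so memory persists early in training.
nn_init_params <- function(shapes, seed) {
  with_local_seed(seed, {
    parts <- lapply(names(shapes), function(nm) {
      d <- shapes[[nm]]
      n <- prod(d)
      if (d[2] == 1L) {  # bias / gain vector
        if (grepl("_gamma$", nm)) {
          rep(1, n)
        } else if (grepl("^lstm[0-9]+_b$", nm)) {
          nh <- n %/% 4L
          b <- rep(0, n)
          b[(nh + 1L):(2L * nh)] <- 1
          b
        } else if (grepl("^head[12]_b$", nm)) {
          # start the sigmoid heads near typical image intensity rather than
          # 0.5 so early epochs are not spent shifting the global level
          rep(stats::qlogis(0.3), n)
        } else {
          rep(0, n)
        }
      } else {
        lim <- sqrt(6 / (d[1] + d[2]))
        stats::runif(n, -lim, lim)
      }
    })
    unlist(parts)
  })
}

nn_param_count <- function(shapes) {
  sum(vapply(shapes, prod, numeric(1)))
}

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  par <- par - lr * mhat / (sqrt(vhat) + eps)
  list(par = par, state = state)
}
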