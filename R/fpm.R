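#' Configuration for the flower-pollination optimizer
#'
#' Canonical flower-pollination-algorithm hyperparameters: population size
#' 20, switch probability 0.8 (global pollination), Levy exponent 1.5, 100
#' iterations.
#'
#' @param population Number of candidate solutions (>= 2).
#' @param switch_p Probability of a global (Levy-flight) move per candidate
#'   per iteration.
#' @param levy_lambda Levy-flight stability exponent.
#' @param iterations Number of iterations.
#' @param bounds Numeric length-2 search interval in Hz.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An `fpm_config` list.
#' @export
fpm_config <- function(population = 20L, switch_p = 0.8,
                       levy_lambda = 1.5, iterations = 100L,
                       bounds = c(0, 125), seed = NULL) {
  stopifnot(population >= 2L, switch_p >= 0, switch_p <= 1,
            iterations >= 1L, length(bounds) == 2L, bounds[1] < bounds[2],
            all(is.finite(bounds)))
  structure(list(population = as.integer(population), switch_p = switch_p,
                 levy_lambda = levy_lambda,
                 iterations = as.integer(iterations),
                 bounds = as.numeric(bounds), seed = seed),
            class = "fpm_config")
}

## Mantegna Levy step for stability exponent lambda
levy_steps <- function(n, lambda) {
  sigma_u <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
                (gamma((1 + lambda) / 2) * lambda *
                   2^((lambda - 1) / 2)))^(1 / lambda)
  u <- stats::rnorm(n, 0, sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / lambda)
}

#' Flower-pollination optimization of a scalar fitness
#'
#' Maximises `fitness` over `config$bounds`. The population is initialized
#' around `seed_point` (which enters the population verbatim, so the
#' best-ever fitness can never fall below the seed's). Each iteration every
#' candidate moves globally with probability `switch_p` via a Mantegna
#' Levy flight toward the current best, `x + L * (g - x)`, and otherwise
#' locally by uniform mixing of two random flowers, `x + eps * (xa - xb)`;
#' moves are clamped to the bounds and accepted greedily.
#'
#' @param fitness Vectorized function Hz -> fitness.
#' @param seed_point Starting frequency in Hz.
#' @param config An [fpm_config()].
#' @return A list with `csv` (best frequency found) and `fitness`.
#' @export
fpm_optimize <- function(fitness, seed_point, config = fpm_config()) {
  if (config$population < 2L) stop("population must be at least 2")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  lo <- config$bounds[1]; hi <- config$bounds[2]
  N <- config$population
  span <- hi - lo
  clamp <- function(x) pmin(pmax(x, lo), hi)
  x <- clamp(c(seed_point,
               seed_point + stats::rnorm(N - 1L, 0, span / 10)))
  fit <- fitness(x)
  best_i <- which.max(fit)
  best_x <- x[best_i]; best_f <- fit[best_i]
  for (it in seq_len(config$iterations)) {
    glob <- stats::runif(N) < config$switch_p
    xn <- x
    if (any(glob)) {
      L <- levy_steps(sum(glob), config$levy_lambda)
      xn[glob] <- x[glob] + L * (best_x - x[glob])
    }
    if (any(!glob)) {
      nl <- sum(!glob)
      a <- sample.int(N, nl, replace = TRUE)
      b <- sample.int(N, nl, replace = TRUE)
      xn[!glob] <- x[!glob] + stats::runif(nl) * (x[a] - x[b])
    }
    xn <- clamp(xn)
    fn <- fitness(xn)
    take <- fn > fit
    x[take] <- xn[take]; fit[take] <- fn[take]
    i <- which.max(fit)
    if (fit[i] > best_f) { best_f <- fit[i]; best_x <- x[i] }
  }
  list(csv = best_x, fitness = best_f)
}
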