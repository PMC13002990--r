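#' Bounded global optimisation
#'
#' A compact differential-evolution optimiser (rand/1/bin with reflection at
#' the box bounds) plus a simulated-annealing fallback via
#' `stats::optim(method = "SANN")` with box clamping. Both are standard
#' general-purpose global search algorithms; they are provided here because
#' the estimation and uncertainty objectives are non-smooth (the L1-penalised
#' constraint relaxation) and need derivative-free bounded search.
#'
#' @param fn objective function of a numeric vector; must return a finite
#'   scalar or `Inf`.
#' @param lower,upper box bounds (numeric vectors of equal length).
#' @param seed integer seed; mandatory for reproducibility.
#' @param budget approximate maximum number of objective evaluations.
#' @param start optional start vector; injected into the initial population.
#' @param method `"de"` (default) or `"sann"`.
#' @param popsize population size (DE only); default `max(10, 4 * d)`.
#' @param F,CR DE differential weight and crossover rate.
#' @param tol early-stopping tolerance on the population cost spread.
#' @return list with `par`, `value`, `evals`, `trace` (best cost per
#'   generation).
#' @export
globalOptim <- function(fn, lower, upper, seed, budget = 2000, start = NULL,
                        method = c("de", "sann"), popsize = NULL,
                        F = 0.8, CR = 0.9, tol = 0) {
  method <- match.arg(method)
  stopifnot(length(lower) == length(upper), all(upper > lower))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  d <- length(lower)
  set.seed(as.integer(seed))

  if (method == "sann") {
    if (is.null(start)) start <- (lower + upper) / 2
    clampfn <- function(x) fn(pmin(pmax(x, lower), upper))
    res <- stats::optim(start, clampfn, method = "SANN",
                        control = list(maxit = budget))
    return(list(par = pmin(pmax(res$par, lower), upper), value = res$value,
                evals = budget, trace = res$value))
  }

  NP <- if (is.null(popsize)) max(10L, 4L * d) else as.integer(popsize)
  pop <- matrix(stats::runif(NP * d, lower, upper), nrow = NP, byrow = TRUE)
  if (!is.null(start)) pop[1, ] <- pmin(pmax(start, lower), upper)
  cost <- apply(pop, 1, fn)
  evals <- NP
  trace <- min(cost)
  while (evals + NP <= budget) {
    for (j in seq_len(NP)) {
      idx <- sample(setdiff(seq_len(NP), j), 3)
      mut <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      # reflect into the box
      below <- mut < lower; mut[below] <- 2 * lower[below] - mut[below]
      above <- mut > upper; mut[above] <- 2 * upper[above] - mut[above]
      mut <- pmin(pmax(mut, lower), upper)
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mut, pop[j, ])
      cv <- fn(trial)
      evals <- evals + 1
      if (is.finite(cv) && cv <= cost[j]) {
        pop[j, ] <- trial
        cost[j] <- cv
      }
    }
    trace <- c(trace, min(cost))
    if (tol > 0 && diff(range(cost[is.finite(cost)])) < tol) break
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], evals = evals, trace = trace)
}
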