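#' Differential evolution over box bounds
#'
#' Classic DE/rand/1/bin with reflection at the bounds, used for SUSTAIN
#' maximum-likelihood fitting. Population defaults to 15 x the number of
#' parameters; runs up to `max_gen` generations with early stopping once the
#' population's objective spread is negligible relative to the best value.
#'
#' @param fn Objective to minimize (takes a numeric vector).
#' @param lower,upper Named numeric bound vectors of equal length.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param pop_size Population size (default `15 * length(lower)`).
#' @param max_gen Maximum generations.
#' @param F Differential weight.
#' @param CR Crossover probability.
#' @param reltol Relative objective spread below which (sustained for 10
#'   generations) the search stops.
#' @return List with `par` (named best parameters), `value`, `generations`,
#'   `n_eval`, and `converged`.
#' @export
de_optimize <- function(fn, lower, upper, seed = 1L,
                        pop_size = 15L * length(lower), max_gen = 300L,
                        F = 0.8, CR = 0.9, reltol = 1e-6) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  dims <- length(lower)
  with_seed(seed, {
    pop <- matrix(runif(pop_size * dims), pop_size, dims)
    pop <- sweep(sweep(pop, 2L, upper - lower, "*"), 2L, lower, "+")
    fit <- apply(pop, 1L, fn)
    n_eval <- pop_size
    gen <- 0L
    calm <- 0L
    converged <- FALSE
    while (gen < max_gen) {
      gen <- gen + 1L
      for (i in seq_len(pop_size)) {
        idx <- sample(setdiff(seq_len(pop_size), i), 3L)
        mutant <- pop[idx[1L], ] + F * (pop[idx[2L], ] - pop[idx[3L], ])
        # reflect back into the box
        over <- mutant > upper
        mutant[over] <- upper[over] - (mutant[over] - upper[over])
        under <- mutant < lower
        mutant[under] <- lower[under] + (lower[under] - mutant[under])
        mutant <- pmin(pmax(mutant, lower), upper)
        cross <- runif(dims) < CR
        cross[sample.int(dims, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        f_trial <- fn(trial)
        n_eval <- n_eval + 1L
        if (f_trial <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- f_trial
        }
      }
      spread <- (max(fit) - min(fit)) / (abs(min(fit)) + reltol)
      calm <- if (spread < reltol) calm + 1L else 0L
      if (calm >= 10L) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(fit)
    par <- pop[best, ]
    names(par) <- names(lower)
    list(par = par, value = fit[best], generations = gen, n_eval = n_eval,
         converged = converged || gen < max_gen)
  })
}
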