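#' Particle swarm configuration
#'
#' Defaults follow the experimental setup used throughout this package for
#' LS-SVM hyperparameter search: 25 particles, inertia weight
#' \eqn{\omega = 0.75}, cognitive and social factors \eqn{c_1 = c_2 = 2},
#' and a search box of \eqn{[-4, 12]} per dimension in log2 units — i.e.
#' \eqn{\gamma, \sigma^2 \in [2^{-4}, 2^{12}]} when the two dimensions are
#' log2(gamma) and log2(sigma2).
#'
#' @param n_particles Number of particles (>= 1).
#' @param inertia Inertia weight \eqn{\omega} (>= 0); trades global
#'   exploration against local refinement.
#' @param c1,c2 Cognitive (personal-best) and social (global-best)
#'   acceleration constants.
#' @param bounds M x 2 matrix of per-dimension closed `[lower, upper]`
#'   intervals; positions and velocities are clamped to this box.
#' @param max_iterations Iteration budget for [pso_optimize()].
#' @param seed Integer seed; the whole trajectory is reproducible from it.
#' @return Object of class `"swarm_config"`.
#' @export
swarm_config <- function(n_particles = 25L, inertia = 0.75, c1 = 2, c2 = 2,
                         bounds = cbind(c(-4, -4), c(12, 12)),
                         max_iterations = 50L, seed = 1L) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1L] >= bounds[, 2L]))
    stopf("bounds must be an M x 2 matrix with lower < upper per dimension")
  if (n_particles < 1L) stopf("n_particles must be >= 1")
  if (inertia < 0) stopf("inertia must be >= 0")
  if (max_iterations < 1L) stopf("max_iterations must be >= 1")
  structure(list(n_particles = as.integer(n_particles), inertia = inertia,
                 c1 = c1, c2 = c2, bounds = bounds,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "swarm_config")
}

eval_fitness <- function(fitness, positions) {
  vapply(seq_len(nrow(positions)), function(i) {
    pos <- positions[i, ]
    val <- tryCatch(fitness(pos), error = function(e)
      stopf("fitness evaluation failed at position (%s): %s",
            paste(format(pos), collapse = ", "), conditionMessage(e)))
    if (!is.numeric(val) || length(val) != 1L || is.na(val))
      stopf("fitness must return a single non-NA number at position (%s)",
            paste(format(pos), collapse = ", "))
    as.numeric(val)
  }, numeric(1))
}

# Update a best record (position/fitness) from a candidate; strict
# improvement wins, exact ties defer to tie_breaker(candidate, incumbent).
better_than <- function(cand_fit, inc_fit, cand_pos, inc_pos, tie_breaker) {
  if (cand_fit > inc_fit) return(TRUE)
  if (cand_fit == inc_fit && !is.null(tie_breaker))
    return(isTRUE(tie_breaker(cand_pos, inc_pos)))
  FALSE
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly over the bounds with the configured seed;
#' velocities start at zero; each personal best is the initial position and
#' the global best is the fittest of them (maximization).
#'
#' @param config A [swarm_config()].
#' @param fitness Function `f(position) -> scalar` to maximize; must be
#'   evaluable anywhere in the bounds.
#' @param tie_breaker Optional `function(candidate, incumbent) -> logical`
#'   preferring the candidate position on exactly equal fitness.
#' @return Object of class `"swarm"` holding positions, velocities,
#'   personal/global bests, the RNG state, and the iteration counter.
#' @export
initialize_swarm <- function(config, fitness, tie_breaker = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  m <- nrow(config$bounds)
  n <- config$n_particles
  state <- with_seed(config$seed, {
    pos <- sapply(seq_len(m), function(j)
      stats::runif(n, config$bounds[j, 1L], config$bounds[j, 2L]))
    pos <- matrix(pos, nrow = n, ncol = m)
    list(positions = pos, rng = get(".Random.seed", envir = globalenv()))
  })
  positions <- state$positions
  pfit <- eval_fitness(fitness, positions)
  gbest <- 1L
  for (i in seq_len(n)[-1L])
    if (better_than(pfit[i], pfit[gbest], positions[i, ], positions[gbest, ],
                    tie_breaker)) gbest <- i
  structure(list(positions = positions,
                 velocities = matrix(0, n, m),
                 pbest = positions, pbest_fitness = pfit,
                 gbest = positions[gbest, ], gbest_fitness = pfit[gbest],
                 config = config, tie_breaker = tie_breaker,
                 rng_state = state$rng, iteration = 0L),
            class = "swarm")
}

#' Advance a swarm one iteration
#'
#' Velocities follow the canonical update
#' \eqn{V \leftarrow \omega V + c_1 r_1 (P - \lambda) + c_2 r_2 (G - \lambda)}
#' with `r1`, `r2` drawn independently per particle and per dimension.
#' Velocities are clamped to the box width per dimension; positions leaving
#' the box are clamped to its boundary with the velocity zeroed in the
#' offending dimension. Personal and global bests are updated on strict
#' fitness improvement.
#'
#' @param swarm A `"swarm"` from [initialize_swarm()].
#' @param fitness The fitness contract (see [initialize_swarm()]).
#' @return The advanced `"swarm"`; `gbest_fitness` never decreases.
#' @export
pso_step <- function(swarm, fitness) {
  stopifnot(inherits(swarm, "swarm"))
  cfg <- swarm$config
  n <- cfg$n_particles
  m <- nrow(cfg$bounds)
  lower <- matrix(cfg$bounds[, 1L], n, m, byrow = TRUE)
  upper <- matrix(cfg$bounds[, 2L], n, m, byrow = TRUE)
  vmax <- upper - lower

  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old_rng <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", swarm$rng_state, envir = globalenv())
  r1 <- matrix(stats::runif(n * m), n, m)
  r2 <- matrix(stats::runif(n * m), n, m)
  swarm$rng_state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old_rng, envir = globalenv())

  gmat <- matrix(swarm$gbest, n, m, byrow = TRUE)
  v <- cfg$inertia * swarm$velocities +
    cfg$c1 * r1 * (swarm$pbest - swarm$positions) +
    cfg$c2 * r2 * (gmat - swarm$positions)
  v <- pmin(pmax(v, -vmax), vmax)
  pos <- swarm$positions + v
  out_low <- pos < lower
  out_high <- pos > upper
  v[out_low | out_high] <- 0
  pos <- pmin(pmax(pos, lower), upper)

  fit <- eval_fitness(fitness, pos)
  for (i in seq_len(n)) {
    if (better_than(fit[i], swarm$pbest_fitness[i], pos[i, ],
                    swarm$pbest[i, ], swarm$tie_breaker)) {
      swarm$pbest[i, ] <- pos[i, ]
      swarm$pbest_fitness[i] <- fit[i]
    }
    if (better_than(swarm$pbest_fitness[i], swarm$gbest_fitness,
                    swarm$pbest[i, ], swarm$gbest, swarm$tie_breaker)) {
      swarm$gbest <- swarm$pbest[i, ]
      swarm$gbest_fitness <- swarm$pbest_fitness[i]
    }
  }
  swarm$positions <- pos
  swarm$velocities <- v
  swarm$iteration <- swarm$iteration + 1L
  swarm
}

#' Particle swarm maximization
#'
#' Runs [initialize_swarm()] and `max_iterations` calls of [pso_step()],
#' tracking the best-so-far fitness after initialization and after every
#' iteration. Fully reproducible from `config$seed`.
#'
#' @inheritParams initialize_swarm
#' @return List with `position` (the global best), `fitness` (its value),
#'   and `history` (length `max_iterations + 1`, non-decreasing).
#' @examples
#' f <- function(p) -(p[1] - 3)^2 - (p[2] + 1)^2
#' cfg <- swarm_config(bounds = cbind(c(-10, -10), c(10, 10)), seed = 7)
#' pso_optimize(f, cfg)$position # close to (3, -1)
#' @export
pso_optimize <- function(fitness, config = swarm_config(),
                         tie_breaker = NULL) {
  swarm <- initialize_swarm(config, fitness, tie_breaker)
  history <- numeric(config$max_iterations + 1L)
  history[1L] <- swarm$gbest_fitness
  for (k in seq_len(config$max_iterations)) {
    swarm <- pso_step(swarm, fitness)
    history[k + 1L] <- swarm$gbest_fitness
  }
  list(position = swarm$gbest, fitness = swarm$gbest_fitness,
       history = history)
}
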