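# Golden Jackal Optimization (GJO) and War Strategy Optimization (WARSO).
#
# Both are population metaheuristics over a bounded continuous space, run
# here as *maximizers* (fitness = classification F1 in the wrapper use).
#
# GJO: the best (male) and second-best (female) jackals steer every other
# member (the prey of its own update). Prey energy E = E1*E0 with
# E0 ~ U(-1, 1) scaled by 2r-1 and E1 = c1*(1 - t/T) decaying linearly;
# |E| >= 1 selects the exploration move
#   Y1 = YM - E*|YM - RL*Prey|,  Y2 = YFM - E*|YFM - RL*Prey|
# and |E| < 1 the exploitation move
#   Y1 = YM - E*|RL*YM - Prey|,  Y2 = YFM - E*|RL*YFM - Prey|,
# with RL a Levy-flight random vector; the candidate moves to (Y1+Y2)/2 and
# is kept only on strict fitness improvement.
#
# WARSO: soldiers follow the King (best) and Commander (second best). Each
# soldier attacks (prob. attack_probability)
#   P <- P + 2*rho*(C - King) + R*(W*King - P)
# or defends
#   P <- P + 2*rho*(King - P_rand) + R*W*(C - P)
# with rho, R ~ U(0,1). A move is accepted only if fitness does not
# decrease; acceptance promotes the soldier's rank and decays its weight
# W <- W*(1 - rank/max_iter)^alpha. After each sweep the single worst
# soldier is relocated toward the army median and the King
# (P_w <- -(1 - R_g)*(P_w - median(P)) + King, R_g ~ N(0,1)), or uniformly
# at random when `weak_relocation = "random"`.

#' Levy-flight step vector (Mantegna construction)
#'
#' `step = scale * u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and `sigma_u` the standard Mantegna scale for `beta`,
#' giving heavy-tailed steps. Uses the current RNG stream.
#'
#' @param dim number of components.
#' @param beta stability exponent, `1 < beta <= 2` (default 1.5).
#' @param scale step scale (default 0.01).
#' @return numeric vector of length `dim`.
#' @export
levy_flight <- function(dim, beta = 1.5, scale = 0.01) {
  stopifnot(beta > 1, beta <= 2)
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(dim, 0, sigma_u)
  v <- stats::rnorm(dim)
  scale * u / abs(v)^(1 / beta)
}

#' One GJO pair move (pure arithmetic, before clamping)
#'
#' @param ym,yfm male (best) and female (second-best) jackal positions.
#' @param prey position being updated.
#' @param E prey energy (scalar).
#' @param rl Levy random vector (same length as the positions).
#' @param exploring logical: `TRUE` applies the exploration move, `FALSE` the
#'   exploitation move.
#' @return list with the two jackal proposals `y1`, `y2` and their average
#'   `new` (the candidate's next position).
#' @export
gjo_move <- function(ym, yfm, prey, E, rl, exploring) {
  if (exploring) {
    y1 <- ym - E * abs(ym - rl * prey)
    y2 <- yfm - E * abs(yfm - rl * prey)
  } else {
    y1 <- ym - E * abs(rl * ym - prey)
    y2 <- yfm - E * abs(rl * yfm - prey)
  }
  list(y1 = y1, y2 = y2, new = (y1 + y2) / 2)
}

#' WARSO attack and defense moves (pure arithmetic, before clamping)
#'
#' @param p soldier position; `king`, `commander`, `p_rand` reference
#'   positions; `rho`, `R` scalars in `[0, 1]`; `w` the soldier's weight.
#' @return proposed position vector.
#' @export
warso_attack <- function(p, king, commander, rho, R, w) {
  p + 2 * rho * (commander - king) + R * (w * king - p)
}

#' @rdname warso_attack
#' @export
warso_defense <- function(p, king, p_rand, commander, rho, R, w) {
  p + 2 * rho * (king - p_rand) + R * w * (commander - p)
}

rank2 <- function(fitness) {
  ord <- order(fitness, decreasing = TRUE)
  list(best = ord[1L], second = if (length(ord) > 1L) ord[2L] else ord[1L])
}

eval_fitness <- function(objective, position) {
  f <- objective(position)
  if (length(f) != 1L || !is.numeric(f)) {
    warning("objective returned a non-scalar value; candidate discarded")
    return(NA_real_)
  }
  if (!is.finite(f)) {
    warning("objective returned non-finite fitness; candidate discarded")
    return(NA_real_)
  }
  f
}

#' Construct a GJO optimizer state
#'
#' @param positions population matrix (rows = members), already within bounds.
#' @param fitness numeric vector of evaluated fitness values.
#' @param space a [search_space()].
#' @param epochs planned number of iterations T.
#' @param c1 energy decay constant (default 1.5).
#' @param levy_beta,levy_scale Levy-flight parameters.
#' @return object of class `gjo_state`.
#' @export
gjo_state <- function(positions, fitness, space, epochs,
                      c1 = 1.5, levy_beta = 1.5, levy_scale = 0.01) {
  stopifnot(nrow(positions) == length(fitness), nrow(positions) >= 2)
  rk <- rank2(fitness)
  structure(
    list(positions = positions, fitness = fitness, space = space,
         t = 0L, epochs = as.integer(epochs),
         male = positions[rk$best, ], female = positions[rk$second, ],
         male_fitness = fitness[rk$best], female_fitness = fitness[rk$second],
         c1 = c1, levy_beta = levy_beta, levy_scale = levy_scale,
         n_explore = 0L, n_exploit = 0L),
    class = "gjo_state"
  )
}

#' Advance a GJO state by one iteration
#'
#' @param state a [gjo_state()].
#' @param objective function(position) -> scalar fitness (maximized).
#' @return the updated state (`t` incremented; male/female re-ranked).
#' @export
gjo_step <- function(state, objective) {
  stopifnot(inherits(state, "gjo_state"), state$t < state$epochs)
  d <- ncol(state$positions)
  E1 <- state$c1 * (1 - state$t / state$epochs)
  for (i in seq_len(nrow(state$positions))) {
    prey <- state$positions[i, ]
    E0 <- 2 * stats::runif(1) - 1
    E <- E1 * E0
    rl <- levy_flight(d, state$levy_beta, state$levy_scale)
    exploring <- abs(E) >= 1
    if (exploring) state$n_explore <- state$n_explore + 1L
    else state$n_exploit <- state$n_exploit + 1L
    cand <- clamp_position(
      gjo_move(state$male, state$female, prey, E, rl, exploring)$new,
      state$space
    )
    f <- eval_fitness(objective, cand)
    if (!is.na(f) && f > state$fitness[i]) {   # greedy replacement
      state$positions[i, ] <- cand
      state$fitness[i] <- f
    }
  }
  rk <- rank2(state$fitness)
  state$male <- state$positions[rk$best, ]
  state$female <- state$positions[rk$second, ]
  state$male_fitness <- state$fitness[rk$best]
  state$female_fitness <- state$fitness[rk$second]
  state$t <- state$t + 1L
  state
}

#' Construct a WARSO optimizer state
#'
#' Soldiers start with rank 0 and weight 1.
#'
#' @inheritParams gjo_state
#' @param alpha weight-decay exponent (default 0.5).
#' @param attack_probability probability of the attack (vs defense) move per
#'   soldier per iteration (default 0.5).
#' @param weak_relocation `"median"` (retrain toward the army median and the
#'   King) or `"random"` (uniform redraw within bounds).
#' @return object of class `warso_state`.
#' @export
warso_state <- function(positions, fitness, space, epochs,
                        alpha = 0.5, attack_probability = 0.5,
                        weak_relocation = c("median", "random")) {
  stopifnot(nrow(positions) == length(fitness), nrow(positions) >= 2)
  weak_relocation <- match.arg(weak_relocation)
  rk <- rank2(fitness)
  structure(
    list(positions = positions, fitness = fitness, space = space,
         t = 0L, epochs = as.integer(epochs),
         king = positions[rk$best, ], commander = positions[rk$second, ],
         king_fitness = fitness[rk$best],
         rank = rep(0L, nrow(positions)), weight = rep(1, nrow(positions)),
         alpha = alpha, attack_probability = attack_probability,
         weak_relocation = weak_relocation,
         n_accepted = 0L),
    class = "warso_state"
  )
}

#' Advance a WARSO state by one iteration
#'
#' @param state a [warso_state()].
#' @param objective function(position) -> scalar fitness (maximized).
#' @return the updated state (`t` incremented; King/Commander re-ranked;
#'   worst soldier relocated).
#' @export
warso_step <- function(state, objective) {
  stopifnot(inherits(state, "warso_state"))
  n <- nrow(state$positions)
  for (i in seq_len(n)) {
    p <- state$positions[i, ]
    rho <- stats::runif(1)
    R <- stats::runif(1)
    cand <- if (stats::runif(1) < state$attack_probability) {
      warso_attack(p, state$king, state$commander, rho, R, state$weight[i])
    } else {
      pr <- state$positions[sample.int(n, 1L), ]
      warso_defense(p, state$king, pr, state$commander, rho, R, state$weight[i])
    }
    cand <- clamp_position(cand, state$space)
    f <- eval_fitness(objective, cand)
    if (!is.na(f) && f >= state$fitness[i]) {   # accept only non-degrading moves
      state$positions[i, ] <- cand
      state$fitness[i] <- f
      state$rank[i] <- state$rank[i] + 1L
      state$weight[i] <- state$weight[i] *
        max(0, 1 - state$rank[i] / state$epochs)^state$alpha
      state$n_accepted <- state$n_accepted + 1L
    }
  }
  worst <- which.min(state$fitness)
  reloc <- if (state$weak_relocation == "median") {
    med <- apply(state$positions, 2, stats::median)
    rg <- stats::rnorm(1)
    -(1 - rg) * (state$positions[worst, ] - med) + state$king
  } else {
    state$space$lower +
      stats::runif(length(state$space$lower)) * (state$space$upper - state$space$lower)
  }
  reloc <- clamp_position(reloc, state$space)
  f <- eval_fitness(objective, reloc)
  if (!is.na(f)) {
    state$positions[worst, ] <- reloc
    state$fitness[worst] <- f
  }
  state$relocated <- worst
  rk <- rank2(state$fitness)
  state$king <- state$positions[rk$best, ]
  state$commander <- state$positions[rk$second, ]
  state$king_fitness <- state$fitness[rk$best]
  state$t <- state$t + 1L
  state
}

#' Run a metaheuristic optimization
#'
#' Initialises the population uniformly within bounds, evaluates it, then
#' runs `epochs` iterations of the chosen optimizer. The trajectory records
#' the best fitness seen up to and including each iteration (monotone
#' non-decreasing); the returned best solution attains its maximum.
#' Deterministic given `seed`.
#'
#' @param objective function(position) -> scalar fitness, maximized. To
#'   minimize, negate the objective.
#' @param space a [search_space()].
#' @param method `"gjo"` or `"warso"`.
#' @param population population size (>= 2, default 30).
#' @param epochs iterations (default 50).
#' @param seed integer seed.
#' @param control optional named list overriding optimizer controls
#'   (`c1`, `levy_beta`, `levy_scale`, `alpha`, `attack_probability`,
#'   `weak_relocation`).
#' @return object of class `optimization_result`: `best_position`,
#'   `best_fitness`, `trajectory` (length `epochs`), `evaluations`,
#'   `method`, and the final optimizer `state`.
#' @export
optimize_mha <- function(objective, space, method = c("gjo", "warso"),
                         population = 30L, epochs = 50L, seed = 1L,
                         control = list()) {
  method <- match.arg(method)
  stopifnot(population >= 2, epochs >= 1)
  n_eval <- 0L
  counted <- function(position) {
    n_eval <<- n_eval + 1L
    objective(position)
  }
  with_seed(seed, {
    positions <- t(vapply(seq_len(population), function(i) init_position(space),
                          numeric(length(space$lower))))
    fitness <- vapply(seq_len(population),
                      function(i) eval_fitness(counted, positions[i, ]),
                      numeric(1))
    fitness[is.na(fitness)] <- -Inf
    state <- if (method == "gjo") {
      gjo_state(positions, fitness, space, epochs,
                c1 = control$c1 %||% 1.5,
                levy_beta = control$levy_beta %||% 1.5,
                levy_scale = control$levy_scale %||% 0.01)
    } else {
      warso_state(positions, fitness, space, epochs,
                  alpha = control$alpha %||% 0.5,
                  attack_probability = control$attack_probability %||% 0.5,
                  weak_relocation = control$weak_relocation %||% "median")
    }
    best_i <- which.max(fitness)
    best_position <- positions[best_i, ]
    best_fitness <- fitness[best_i]
    trajectory <- numeric(epochs)
    step_fn <- if (method == "gjo") gjo_step else warso_step
    for (it in seq_len(epochs)) {
      state <- step_fn(state, counted)
      it_best <- which.max(state$fitness)
      if (state$fitness[it_best] > best_fitness) {
        best_fitness <- state$fitness[it_best]
        best_position <- state$positions[it_best, ]
      }
      trajectory[it] <- best_fitness
    }
    structure(
      list(best_position = best_position, best_fitness = best_fitness,
           trajectory = trajectory, evaluations = n_eval,
           method = method, state = state),
      class = "optimization_result"
    )
  })
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>", x$method, "| best fitness",
      signif(x$best_fitness, 6), "|", length(x$trajectory), "iterations |",
      x$evaluations, "evaluations\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
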