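#' SSU-BES configuration
#'
#' Defaults used for classifier weight tuning: population 10, 25 iterations,
#' bounds `[-1, 1]` per weight. `beta` and `Q` are the spiral constants (both
#' constrained to `[0.5, 2]`); `it1`/`it2` scale the swoop attractors; `eta`
#' (search/swoop gain) anneals linearly from 1 to 0.1 and the inertia `alpha`
#' from 0.9 to 0.4 across iterations. The chaotic draw `R1` comes from the
#' circle map `x' = (x + b - a/(2*pi) * sin(2*pi*x)) mod 1`.
#'
#' @param dim Solution dimension.
#' @param pop Population size.
#' @param iters Iteration budget.
#' @param bounds Length-2 lower/upper position bounds.
#' @param beta,Q Spiral constants in `[0.5, 2]`.
#' @param it1,it2 Swoop attractor multipliers in `[1, 2]`.
#' @param eta_range,alpha_range Linear schedule end-points (start, end).
#' @param circle_a,circle_b,circle_x0 Circle-map parameters and state seed.
#' @param chaotic_polar Use the deterministic arctan/arccos polar angles in
#'   the search spiral instead of random draws.
#' @param eps_grad Magnitude floor for the secant gradient estimate and the
#'   swoop denominator.
#' @param seed RNG seed (runs are deterministic given it).
#' @return An `ssu_bes_config` list.
#' @export
ssu_bes_config <- function(dim, pop = 10L, iters = 25L, bounds = c(-1, 1),
                           beta = 2, Q = 1.5, it1 = 2, it2 = 2,
                           eta_range = c(1, 0.1), alpha_range = c(0.9, 0.4),
                           circle_a = 0.5, circle_b = 0.2, circle_x0 = 0.7,
                           chaotic_polar = FALSE, eps_grad = 1e-8, seed = 1L) {
  if (!(beta >= 0.5 && beta <= 2) || !(Q >= 0.5 && Q <= 2)) {
    abort("beta and Q must lie in [0.5, 2]")
  }
  if (!(it1 >= 1 && it1 <= 2) || !(it2 >= 1 && it2 <= 2)) abort("it1, it2 must lie in [1, 2]")
  if (!all(is.finite(bounds)) || bounds[1] >= bounds[2]) abort("bounds must be finite with lower < upper")
  structure(list(dim = as.integer(dim), pop = as.integer(pop), iters = as.integer(iters),
                 bounds = bounds, beta = beta, Q = Q, it1 = it1, it2 = it2,
                 eta_range = eta_range, alpha_range = alpha_range,
                 circle_a = circle_a, circle_b = circle_b, circle_x0 = circle_x0,
                 chaotic_polar = isTRUE(chaotic_polar), eps_grad = eps_grad,
                 seed = as.integer(seed)),
            class = "ssu_bes_config")
}

#' Circle-map iteration
#'
#' One step of the chaotic circle map
#' `x' = (x + b - a/(2*pi) * sin(2*pi*x)) mod 1`, used as a deterministic
#' pseudo-random source for the `R1` draws.
#'
#' @param x Current state in `[0, 1)`.
#' @param a,b Map parameters.
#' @return Next state in `[0, 1)`.
#' @export
circle_map_next <- function(x, a = 0.5, b = 0.2) {
  (x + b - (a / (2 * pi)) * sin(2 * pi * x)) %% 1
}

circle_map_draws <- function(state, n, a, b) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- circle_map_next(state, a, b)
    out[i] <- state
  }
  list(draws = out, state = state)
}

#' Weighted sample standard deviation
#'
#' `sqrt( sum w_i (z_i - zbar_w)^2 / ( ((K'-1)/K') * sum w_i ) )` with
#' `zbar_w` the weighted mean and `K'` the number of strictly positive
#' weights. Scale-invariant in the weights; 0 when all observations coincide
#' or only one weight is active.
#'
#' @param z Observations.
#' @param w Nonnegative weights, not all zero.
#' @return Nonnegative scalar.
#' @export
weighted_std <- function(z, w) {
  if (length(z) != length(w)) abort("z and w must have equal length")
  if (any(w < 0)) abort("weights must be nonnegative")
  if (all(w == 0)) abort("weights must not be all zero")
  kp <- sum(w > 0)
  if (kp < 2) return(0)
  zbar <- sum(w * z) / sum(w)
  sqrt(sum(w * (z - zbar)^2) / (((kp - 1) / kp) * sum(w)))
}

#' Space-selection proposals
#'
#' `Z_new_i = Z_best + beta * ra_i * (Z_mean - Z_i)`, clipped to bounds.
#'
#' @param Z Position matrix (population x dim).
#' @param z_best Best-ever position.
#' @param z_mean Population mean position.
#' @param beta Controlling constant.
#' @param ra Per-eagle uniform draws in `[0, 1]`.
#' @param bounds Length-2 bounds.
#' @return Proposed position matrix.
#' @export
select_space <- function(Z, z_best, z_mean, beta, ra = runif(nrow(Z)),
                         bounds = c(-Inf, Inf)) {
  prop <- sweep((matrix(z_mean, nrow(Z), ncol(Z), byrow = TRUE) - Z) * (beta * ra),
                2, z_best, `+`)
  clip(prop, bounds[1], bounds[2])
}

#' Spiral coefficients for the search and swoop stages
#'
#' Search phase: `pr = cos(theta) * ran`, `Yr = sin(theta) * ran` with
#' `theta = beta * pi * ran1` and `ran = theta + Q * ran2`; with
#' `chaotic_polar` the deterministic alternates
#' `theta = (2/pi) * acos((1/3) * atan(it))`, `ran = (1/2) * atan(it)` are
#' used. Swoop phase: `pr = ran * sinh(theta)`, `Yr = ran * cosh(theta)` with
#' `theta = beta * pi * ran3`, `ran = theta`. Both `pr` and `Yr` are
#' normalised by the population maximum of their absolute values (all-zero
#' normaliser yields all-zero coefficients).
#'
#' @param n Population size.
#' @param beta,Q Spiral constants.
#' @param phase `"search"` or `"swoop"`.
#' @param chaotic_polar Use the deterministic polar angles (search phase).
#' @param it Iteration index (used by the deterministic angles).
#' @param draws Optional list of uniform draws `ran1`, `ran2`, `ran3` (each
#'   length `n`); drawn from the RNG when omitted.
#' @return List with normalised `p`, `Y` and raw `pr`, `Yr`, `theta`, `ran`.
#' @export
spiral_coeffs <- function(n, beta = 2, Q = 1.5, phase = c("search", "swoop"),
                          chaotic_polar = FALSE, it = 1, draws = NULL) {
  phase <- match.arg(phase)
  if (phase == "search") {
    if (chaotic_polar) {
      theta <- rep((2 / pi) * acos((1 / 3) * atan(it)), n)
      ran <- rep((1 / 2) * atan(it), n)
    } else {
      ran1 <- draws$ran1 %||% runif(n)
      ran2 <- draws$ran2 %||% runif(n)
      theta <- beta * pi * ran1
      ran <- theta + Q * ran2
    }
    pr <- cos(theta) * ran
    Yr <- sin(theta) * ran
  } else {
    ran3 <- draws$ran3 %||% runif(n)
    theta <- beta * pi * ran3
    ran <- theta
    pr <- ran * sinh(theta)
    Yr <- ran * cosh(theta)
  }
  norm1 <- function(v) {
    m <- max(abs(v))
    if (m == 0) rep(0, length(v)) else v / m
  }
  list(p = norm1(pr), Y = norm1(Yr), pr = pr, Yr = Yr, theta = theta, ran = ran)
}

#' Shark-smell-updated spiral search proposals
#'
#' `Z_new_i = eta_k * R1_i * (Z_i + Y_i (Z_i - Z_{i+1})) / g_i
#'  + p_i * (Z_i - Z_mean)` with cyclic neighbour `i+1`, `R1` from the circle
#' map, and `g_i` a guarded scalar secant gradient estimate (magnitude floored
#' at `eps`). Clipped to bounds.
#'
#' @param Z Position matrix.
#' @param coeffs List with `p`, `Y` (see [spiral_coeffs()]).
#' @param g Per-eagle gradient estimates.
#' @param eta_k Gain schedule value.
#' @param R1 Per-eagle circle-map draws.
#' @param z_mean Population mean position.
#' @param bounds Length-2 bounds.
#' @param eps Gradient magnitude floor.
#' @return Proposed position matrix.
#' @export
search_update <- function(Z, coeffs, g, eta_k, R1, z_mean, bounds = c(-Inf, Inf),
                          eps = 1e-8) {
  n <- nrow(Z)
  nb <- Z[c(2:n, 1)[seq_len(n)], , drop = FALSE]
  g <- ifelse(abs(g) < eps, eps * ifelse(g < 0, -1, 1), g)
  spiral <- Z + coeffs$Y * (Z - nb)
  prop <- (eta_k * R1 / g) * spiral +
    coeffs$p * sweep(Z, 2, z_mean, `-`)
  clip(prop, bounds[1], bounds[2])
}

# Plain BES search (no shark terms).
bes_search_update <- function(Z, coeffs, z_mean, bounds = c(-Inf, Inf)) {
  n <- nrow(Z)
  nb <- Z[c(2:n, 1)[seq_len(n)], , drop = FALSE]
  prop <- Z + coeffs$Y * (Z - nb) + coeffs$p * sweep(Z, 2, z_mean, `-`)
  clip(prop, bounds[1], bounds[2])
}

#' Shark-smell-updated swoop proposals
#'
#' Numerator `rand_i * Z_best + p1_i (Z_i - it1 * Z_mean) +
#' Y1_i (Z_i - it2 * Z_best)`; denominator
#' `eta_k * R1_i * g_i + alpha_k * R2_i * V_i` element-wise with a
#' sign-preserving floor; the quotient is scaled by the weighted standard
#' deviation `sd_w` of the population costs and clipped to bounds.
#'
#' @param Z Position matrix.
#' @param z_best,z_mean Best and mean positions.
#' @param coeffs List with `p` (used as `p1`) and `Y` (as `Y1`).
#' @param rand Per-eagle uniform draws.
#' @param g Per-eagle gradient estimates.
#' @param V Velocity matrix (population x dim).
#' @param eta_k,alpha_k Schedule values.
#' @param R1,R2 Per-eagle chaotic / uniform draws.
#' @param sd_w Weighted cost standard deviation.
#' @param it1,it2 Attractor multipliers.
#' @param bounds Length-2 bounds.
#' @param eps Denominator floor.
#' @return Proposed position matrix.
#' @export
swoop_update <- function(Z, z_best, z_mean, coeffs, rand, g, V, eta_k, alpha_k,
                         R1, R2, sd_w, it1 = 2, it2 = 2, bounds = c(-Inf, Inf),
                         eps = 1e-8) {
  n <- nrow(Z)
  num <- rand %o% z_best +
    coeffs$p * (Z - it1 * matrix(z_mean, n, ncol(Z), byrow = TRUE)) +
    coeffs$Y * (Z - it2 * matrix(z_best, n, ncol(Z), byrow = TRUE))
  den <- (eta_k * R1 * g) + alpha_k * R2 * V
  den <- ifelse(abs(den) < eps, eps * ifelse(den < 0, -1, 1), den)
  clip((num / den) * sd_w, bounds[1], bounds[2])
}

# Plain BES swoop (Eq. 25 form).
bes_swoop_update <- function(Z, z_best, z_mean, coeffs, rand, it1 = 2, it2 = 2,
                             bounds = c(-Inf, Inf)) {
  n <- nrow(Z)
  prop <- rand %o% z_best +
    coeffs$p * (Z - it1 * matrix(z_mean, n, ncol(Z), byrow = TRUE)) +
    coeffs$Y * (Z - it2 * matrix(z_best, n, ncol(Z), byrow = TRUE))
  clip(prop, bounds[1], bounds[2])
}

SENTINEL_COST <- 1e6

safe_objective <- function(obj) {
  function(x) {
    val <- tryCatch(obj(x), error = function(e) SENTINEL_COST)
    if (!is.finite(val)) SENTINEL_COST else val
  }
}

# Rank-based observation weights for the shark sd_w term: best cost gets the
# largest weight.
rank_weights <- function(cost) {
  n <- length(cost)
  (n + 1 - rank(cost, ties.method = "first")) / n
}

run_bes_family <- function(obj, config, hybrid) {
  f <- safe_objective(obj)
  cfg <- config
  with_local_seed(cfg$seed, {
    n <- cfg$pop; d <- cfg$dim
    lo <- cfg$bounds[1]; hi <- cfg$bounds[2]
    Z <- matrix(runif(n * d, lo, hi), n, d)
    cost <- apply(Z, 1, f)
    evals <- n
    last_Z <- Z; last_cost <- cost          # pre-move state for the secant
    V <- matrix(runif(n * d, -0.01, 0.01) * (hi - lo), n, d)
    cstate <- cfg$circle_x0
    ib <- which.min(cost)
    z_best <- Z[ib, ]; best_cost <- cost[ib]
    trace <- matrix(0, cfg$iters, 3)

    accept <- function(prop) {
      pc <- apply(prop, 1, f)
      evals <<- evals + n
      better <- pc < cost
      if (any(better)) {
        last_Z[better, ] <<- Z[better, , drop = FALSE]
        last_cost[better] <<- cost[better]
        Z[better, ] <<- prop[better, , drop = FALSE]
        cost[better] <<- pc[better]
        ibn <- which.min(cost)
        if (cost[ibn] < best_cost) {
          best_cost <<- cost[ibn]
          z_best <<- Z[ibn, ]
        }
      }
    }

    for (k in seq_len(cfg$iters)) {
      frac <- if (cfg$iters > 1) (k - 1) / (cfg$iters - 1) else 0
      eta_k <- cfg$eta_range[1] + frac * (cfg$eta_range[2] - cfg$eta_range[1])
      alpha_k <- cfg$alpha_range[1] + frac * (cfg$alpha_range[2] - cfg$alpha_range[1])
      Z_start <- Z

      # stage 1: select space
      z_mean <- colMeans(Z)
      accept(select_space(Z, z_best, z_mean, cfg$beta, runif(n), cfg$bounds))

      # stage 2: spiral search
      z_mean <- colMeans(Z)
      sc <- spiral_coeffs(n, cfg$beta, cfg$Q, "search",
                          chaotic_polar = cfg$chaotic_polar, it = k)
      if (hybrid) {
        g <- (cost - last_cost) / (sqrt(rowSums((Z - last_Z)^2)) + cfg$eps_grad)
        cd <- circle_map_draws(cstate, n, cfg$circle_a, cfg$circle_b)
        cstate <- cd$state
        accept(search_update(Z, sc, g, eta_k, cd$draws, z_mean, cfg$bounds, cfg$eps_grad))
      } else {
        accept(bes_search_update(Z, sc, z_mean, cfg$bounds))
      }

      # stage 3: swoop
      z_mean <- colMeans(Z)
      sw <- spiral_coeffs(n, cfg$beta, cfg$Q, "swoop")
      rand <- runif(n)
      if (hybrid) {
        g <- (cost - last_cost) / (sqrt(rowSums((Z - last_Z)^2)) + cfg$eps_grad)
        cd <- circle_map_draws(cstate, n, cfg$circle_a, cfg$circle_b)
        cstate <- cd$state
        sd_w <- weighted_std(cost, rank_weights(cost))
        accept(swoop_update(Z, z_best, z_mean, sw, rand, g, V, eta_k, alpha_k,
                            cd$draws, runif(n), sd_w, cfg$it1, cfg$it2,
                            cfg$bounds, cfg$eps_grad))
      } else {
        accept(bes_swoop_update(Z, z_best, z_mean, sw, rand, cfg$it1, cfg$it2, cfg$bounds))
      }

      V <- Z - Z_start
      trace[k, ] <- c(best_cost, mean(cost), evals)
    }

    structure(list(
      best = z_best, best_cost = best_cost,
      trace = tibble::tibble(iteration = seq_len(cfg$iters),
                             best_cost = trace[, 1], mean_cost = trace[, 2],
                             evals = as.integer(trace[, 3])),
      evals = evals, config = cfg,
      method = if (hybrid) "ssu-bes" else "bes"
    ), class = "optim_result")
  })
}

#' Run the hybrid SSU-BES optimizer
#'
#' Per iteration each eagle passes through three stages — space selection,
#' shark-smell-updated spiral search, and shark-smell-updated swoop — with
#' greedy acceptance after every stage, so the best-cost trace is monotone
#' non-increasing. Objective failures or non-finite costs are absorbed as a
#' sentinel cost of `1e6` and the run continues. Deterministic given
#' `config$seed`.
#'
#' @param obj Objective callable mapping a numeric vector of length
#'   `config$dim` to a scalar cost.
#' @param config An [ssu_bes_config()].
#' @return An `optim_result` list: `best` (position), `best_cost`, `trace`
#'   (tibble of iteration, best_cost, mean_cost, evals), `evals`, `config`,
#'   `method`.
#' @export
run_ssu_bes <- function(obj, config) run_bes_family(obj, config, hybrid = TRUE)

#' Run plain bald eagle search (ablation baseline)
#'
#' The same three-stage loop as [run_ssu_bes()] using the unmodified search
#' and swoop updates (no chaotic draws, gradient scaling, velocity damping, or
#' weighted-deviation scaling).
#'
#' @inheritParams run_ssu_bes
#' @return An `optim_result`.
#' @export
run_bes <- function(obj, config) run_bes_family(obj, config, hybrid = FALSE)

#' Uniform random search over the bounds (floor baseline)
#'
#' Spends the same evaluation budget as a three-stage [run_ssu_bes()] run
#' (`pop * (1 + 3 * iters)` evaluations) on i.i.d. uniform samples.
#'
#' @inheritParams run_ssu_bes
#' @return An `optim_result`.
#' @export
run_random_search <- function(obj, config) {
  f <- safe_objective(obj)
  cfg <- config
  with_local_seed(cfg$seed, {
    budget <- cfg$pop * (1 + 3 * cfg$iters)
    best_cost <- Inf; z_best <- NULL
    trace_best <- numeric(cfg$iters)
    trace_mean <- numeric(cfg$iters)
    per_iter <- ceiling(budget / cfg$iters)
    evals <- 0
    for (k in seq_len(cfg$iters)) {
      m <- min(per_iter, budget - evals)
      if (m <= 0) m <- 1
      X <- matrix(runif(m * cfg$dim, cfg$bounds[1], cfg$bounds[2]), m, cfg$dim)
      cs <- apply(X, 1, f)
      evals <- evals + m
      ib <- which.min(cs)
      if (cs[ib] < best_cost) {
        best_cost <- cs[ib]; z_best <- X[ib, ]
      }
      trace_best[k] <- best_cost
      trace_mean[k] <- mean(cs)
    }
    structure(list(best = z_best, best_cost = best_cost,
                   trace = tibble::tibble(iteration = seq_len(cfg$iters),
                                          best_cost = trace_best,
                                          mean_cost = trace_mean,
                                          evals = seq_len(cfg$iters) * per_iter),
                   evals = evals, config = cfg, method = "random"),
              class = "optim_result")
  })
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("<optim_result: %s> dim %d, %d evals, best cost %.6g\n",
              x$method, x$config$dim, x$evals, x$best_cost))
  invisible(x)
}

#' Reciprocal-accuracy training objective
#'
#' Builds the cost function the optimizer minimises: decode the solution
#' vector into the tri-classifier bundle, predict the held-out split, and
#' return `1 / max(accuracy, 1e-6)` (so perfect accuracy attains the minimum
#' cost of 1 and zero accuracy the sentinel `1e6`).
#'
#' @param features Numeric matrix (trials x features), already normalised.
#' @param labels Binary labels (0/1) for those trials.
#' @param template A [tri_classifier_params()] bundle to decode into.
#' @return A function `f(solution_vector) -> cost`.
#' @export
tri_objective <- function(features, labels, template) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  function(vec) {
    params <- decode_solution(vec, template)
    pred <- ensemble_predict_batch(features, params)$label
    acc <- mean(pred == labels)
    1 / max(acc, 1e-6)
  }
}
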