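#' Run one generation of the virtual-arrowhead task
#'
#' Executes a full `T`-trial session for a single win-stay/lose-shift agent
#' following the alternating allocation schedule: exploitation on trial 1,
#' exploration on even trials up to `2*tau`, exploitation elsewhere.
#' Randomness (initial direction signs, attribute choices, hunting noise)
#' comes from R's global RNG; call [set.seed()] beforehand for a
#' reproducible trajectory.
#'
#' @param schedule An [allocation_schedule], or a raw character vector of
#'   per-trial actions (`"explore"`/`"exploit"`, exploitation forced on
#'   trial 1) for behaviour outside the alternating family — e.g. the
#'   over-exploring participants seen in transmission-chain experiments.
#' @param landscape A [fitness_landscape].
#' @param initial_design Starting design; defaults to the landscape's.
#' @param state Optional pre-built [agent_state] (fresh random one if NULL).
#' @param L Exploration step size (default 5).
#' @return A data frame of class `trajectory`, one row per trial, with
#'   columns `trial`, `action`, `length`, `width`, `thickness`,
#'   `expected_score` (efficiency of the design held at the end of the
#'   trial), `observed_score` (NA on exploration trials) and
#'   `cumulative_score`. The total pay-off `W` (sum of observed scores over
#'   exploitation trials) is attached as attribute `"W"`.
#' @examples
#' set.seed(1)
#' tr <- run_generation(allocation_schedule(12), default_landscape())
#' attr(tr, "W")
#' @export
run_generation <- function(schedule, landscape,
                           initial_design = landscape$initial_design,
                           state = NULL, L = 5L) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  .check_design(initial_design)
  if (is.null(state)) state <- agent_state()
  if (inherits(schedule, "allocation_schedule")) {
    actions <- schedule_actions(schedule)
  } else {
    actions <- .check_actions(schedule)
  }
  T <- length(actions)
  design <- stats::setNames(as.integer(initial_design), .attributes)
  designs <- matrix(NA_integer_, T, 3L, dimnames = list(NULL, .attributes))
  observed <- rep(NA_integer_, T)
  for (trial in seq_len(T)) {
    if (actions[trial] == "explore") {
      step <- explore_step(state, design, L = L)
      design <- step$design
    } else {
      step <- exploit_step(state, design, landscape)
      observed[trial] <- step$score
    }
    state <- step$state
    designs[trial, ] <- design
  }
  out <- data.frame(trial = seq_len(T),
                    action = actions,
                    length = designs[, 1L],
                    width = designs[, 2L],
                    thickness = designs[, 3L],
                    expected_score = .efficiency(landscape, designs),
                    observed_score = observed,
                    cumulative_score = cumsum(ifelse(is.na(observed), 0L, observed)),
                    stringsAsFactors = FALSE)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "W") <- sum(observed, na.rm = TRUE)
  out
}

.check_actions <- function(actions) {
  if (!is.character(actions) || length(actions) < 1L ||
      !all(actions %in% c("explore", "exploit"))) {
    stop("actions must be a character vector of 'explore'/'exploit'",
         call. = FALSE)
  }
  if (actions[1L] != "exploit") {
    stop("the first trial is always exploitation", call. = FALSE)
  }
  actions
}

# Action sequence for an arbitrary exploration count tau in [0, T-1]:
# alternate within the rational family as long as possible (explore on even
# trials up to 2*min(tau, floor((T-1)/2))), then convert trailing
# exploitation trials to exploration for over-exploring individuals.
.tau_actions <- function(tau, T) {
  stopifnot(tau >= 0, tau <= T - 1)
  actions <- rep("exploit", T)
  k <- min(tau, (T - 1L) %/% 2L)
  if (k > 0) actions[seq(2L, 2L * k, by = 2L)] <- "explore"
  extra <- tau - k
  if (extra > 0) {
    free <- setdiff(which(actions == "exploit"), 1L)
    actions[rev(free)[seq_len(extra)]] <- "explore"
  }
  actions
}

#' Run a two-generation transmission chain
#'
#' The final arrowhead design of the first generation becomes the initial
#' design of the second generation, exactly as in the transmission-chain
#' method; the second generation starts with fresh agent memory (new random
#' direction signs, no remembered score).
#'
#' @param tau_first,tau_second Exploration counts for the two generations.
#' @param landscape A [fitness_landscape].
#' @param initial_design First generation's starting design (default: the
#'   landscape's common fixed initial design).
#' @param T Trials per generation (default 50).
#' @param L Exploration step size.
#' @return List with components `first` and `second`, each a `trajectory`.
#' @export
run_chain <- function(tau_first, tau_second, landscape,
                      initial_design = landscape$initial_design,
                      T = 50L, L = 5L) {
  g1 <- run_generation(allocation_schedule(tau_first, T), landscape,
                       initial_design, L = L)
  final <- as.integer(g1[T, c("length", "width", "thickness")])
  g2 <- run_generation(allocation_schedule(tau_second, T), landscape,
                       initial_design = final, L = L)
  list(first = g1, second = g2)
}

#' Estimate the discrete learning curve g(tau)
#'
#' Simulates an ensemble of win-stay/lose-shift agents, all following the
#' maximal alternating schedule (`tau_max = floor((T-1)/2)` explorations),
#' and records the noise-free efficiency of the design held immediately
#' after each exploration trial. Because any shorter schedule coincides
#' with the maximal one up to its switching point, a single pass yields
#' `g(tau)` for every `tau = 0..tau_max` simultaneously: `g(tau)` is the
#' ensemble mean efficiency after `tau` explorations.
#'
#' Each agent draws from its own L'Ecuyer-CMRG substream spawned from
#' `seed` (via [parallel::nextRNGStream()]), so enlarging the ensemble
#' leaves the trajectories of earlier agents unchanged.
#'
#' @param landscape A [fitness_landscape].
#' @param n_agents Ensemble size (default 10,000).
#' @param T Trials per agent (default 50).
#' @param seed Master seed for the ensemble; if `NULL`, one is drawn from
#'   the global RNG.
#' @param L Exploration step size.
#' @param initial_design Common starting design (default: landscape's).
#' @param keep_agents If `TRUE`, attach the full `n_agents x (tau_max+1)`
#'   per-agent efficiency matrix as attribute `"agents"`.
#' @return An object of class `learning_curve_estimate`: a list with
#'   `tau` (0..tau_max), `g` (mean efficiency), `se` (standard errors),
#'   `n_agents`, `T`.
#' @examples
#' g <- estimate_learning_curve(default_landscape(), n_agents = 200, seed = 1)
#' g$g[1]  # efficiency of the common initial design, exactly
#' @export
estimate_learning_curve <- function(landscape, n_agents = 10000L, T = 50L,
                                    seed = NULL, L = 5L,
                                    initial_design = landscape$initial_design,
                                    keep_agents = FALSE) {
  stopifnot(inherits(landscape, "fitness_landscape"), n_agents >= 1)
  .check_design(initial_design)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  tau_max <- (T - 1L) %/% 2L
  n_explore <- tau_max
  n_exploit <- T - tau_max

  # Per-agent draws from independent L'Ecuyer substreams, laid out as
  # matrices: U[, 1:3] initial direction signs, U[, 3 + k] attribute choice
  # of the k-th exploration; Z[, j] hunting noise of the j-th exploitation.
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- .Random.seed
  U <- matrix(0, n_agents, 3L + n_explore)
  Z <- matrix(0, n_agents, n_exploit)
  for (i in seq_len(n_agents)) {
    assign(".Random.seed", s, envir = globalenv())
    U[i, ] <- stats::runif(3L + n_explore)
    Z[i, ] <- stats::rnorm(n_exploit)
    s <- parallel::nextRNGStream(s)
  }

  dir <- ifelse(U[, 1:3] < 0.5, -1, 1)
  design <- matrix(rep(as.numeric(initial_design), each = n_agents),
                   n_agents, 3L)
  eff <- matrix(NA_real_, n_agents, tau_max + 1L)
  eff[, 1L] <- .efficiency(landscape, design)
  last_score <- rep(NA_real_, n_agents)
  last_mod <- rep(NA_integer_, n_agents)
  rows <- seq_len(n_agents)
  tau <- 0L; hunt_i <- 0L
  for (trial in seq_len(T)) {
    if (trial %% 2L == 0L && tau < tau_max) {
      tau <- tau + 1L
      a <- 1L + as.integer(3 * U[, 3L + tau])  # uniform over 1..3
      idx <- cbind(rows, a)
      design[idx] <- pmin(100, pmax(1, design[idx] + L * dir[idx]))
      last_mod <- a
      eff[, tau + 1L] <- .efficiency(landscape, design)
    } else {
      hunt_i <- hunt_i + 1L
      sc <- pmin(1000, pmax(0, round(.efficiency(landscape, design) +
                                       landscape$noise_sd * Z[, hunt_i])))
      flip <- !is.na(last_score) & sc < last_score & !is.na(last_mod)
      if (any(flip)) {
        fidx <- cbind(rows[flip], last_mod[flip])
        dir[fidx] <- -dir[fidx]
      }
      last_score <- sc
    }
  }
  g <- colMeans(eff)
  se <- apply(eff, 2L, stats::sd) / sqrt(n_agents)
  out <- structure(list(tau = 0:tau_max, g = g, se = se,
                        n_agents = as.integer(n_agents), T = as.integer(T)),
                   class = "learning_curve_estimate")
  if (keep_agents) attr(out, "agents") <- eff
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.as_g <- function(g) {
  if (inherits(g, "learning_curve_estimate")) g$g
  else if (is.numeric(g)) as.numeric(g)
  else stop("g must be a learning_curve_estimate or a numeric vector",
            call. = FALSE)
}

#' Expected total pay-off from the learning curve
#'
#' Evaluates the first-generation pay-off implied by a learning curve
#' `g(tau)`: the alternating phase contributes `sum_{tau=0}^{tau_p-1}
#' g(tau)` (one exploitation trial at each efficiency level, empty when
#' `tau_p = 0`), and the exclusive-exploitation phase contributes
#' `(T - 2 tau_p) g(tau_p)` in the unrepaid/asocial condition or
#' `(2T - 2 tau_p) g(tau_p)` in the repaid condition, where the doubled
#' horizon carries the successor's identically weighted earnings.
#'
#' @param g A `learning_curve_estimate` or a numeric vector `g[tau+1] =
#'   g(tau)`, `tau = 0, 1, ...`.
#' @param tau_p Number of exploration trials, `0 <= 2*tau_p <= T-1`.
#' @param T Total trials (default 50).
#' @param condition `"unrepaid"`, `"asocial"` (same pay-off) or `"repaid"`.
#' @return Expected total pay-off in calories.
#' @export
payoff_from_curve <- function(g, tau_p, T = 50L,
                              condition = c("unrepaid", "asocial", "repaid")) {
  condition <- match.arg(condition)
  gv <- .as_g(g)
  stopifnot(tau_p == round(tau_p))
  if (tau_p < 0 || 2 * tau_p > T - 1) {
    stop("tau_p must satisfy 0 <= 2*tau_p <= T - 1", call. = FALSE)
  }
  if (tau_p + 1 > length(gv)) {
    stop("learning curve too short for tau_p = ", tau_p, call. = FALSE)
  }
  horizon <- if (condition == "repaid") 2 * T else T
  sum(gv[seq_len(tau_p)]) + (horizon - 2 * tau_p) * gv[tau_p + 1L]
}

#' Optimal number of exploration trials
#'
#' Maximizes the curve-based expected pay-off over all admissible
#' exploration counts `tau_p = 0..floor((T-1)/2)`. Ties are broken toward
#' the smaller `tau` (less exploration at equal pay-off).
#'
#' @inheritParams payoff_from_curve
#' @return An object of class `tau_optimum`: list with `tau_star`, the
#'   full pay-off vector `payoff`, the per-trial pay-off curve `per_trial`
#'   (`W/T`, as plotted in condition comparisons), `condition` and `T`.
#' @examples
#' g <- estimate_learning_curve(default_landscape(), n_agents = 500, seed = 1)
#' optimal_tau(g, condition = "repaid")$tau_star
#' @export
optimal_tau <- function(g, T = 50L,
                        condition = c("unrepaid", "asocial", "repaid")) {
  condition <- match.arg(condition)
  gv <- .as_g(g)
  tau_max <- min((T - 1L) %/% 2L, length(gv) - 1L)
  taus <- 0:tau_max
  W <- vapply(taus, function(tp) payoff_from_curve(gv, tp, T, condition),
              numeric(1))
  structure(list(tau_star = taus[which.max(W)],
                 tau = taus, payoff = W, per_trial = W / T,
                 condition = condition, T = as.integer(T)),
            class = "tau_optimum")
}

#' Number of admissible allocation strategies
#'
#' With `T` trials and exploitation forced on trial 1, each of the
#' remaining `T - 1` trials is a free binary choice, so there are
#' `2^(T-1)` possible allocation sequences (exact up to `T = 54`, the
#' limit of exact integer representation in doubles). The restriction to
#' the alternating family searched by [optimal_tau()] is what makes the
#' optimization tractable.
#'
#' @param T Number of trials.
#' @return The exact count as a double.
#' @examples
#' count_allocation_strategies(50)  # 2^49
#' @export
count_allocation_strategies <- function(T) {
  stopifnot(T == round(T), T >= 1)
  if (T > 54) stop("exact integer count only representable up to T = 54",
                   call. = FALSE)
  2^(T - 1)
}

#' @export
print.learning_curve_estimate <- function(x, ...) {
  cat(sprintf("Learning curve g(tau), %d agents, T = %d\n", x$n_agents, x$T))
  print(utils::head(data.frame(tau = x$tau, g = round(x$g, 2),
                               se = signif(x$se, 3)), 8))
  if (length(x$tau) > 8) cat("  ...", length(x$tau) - 8, "more rows\n")
  invisible(x)
}

#' @export
print.tau_optimum <- function(x, ...) {
  cat(sprintf("Optimal exploration count (%s): tau* = %d (per-trial pay-off %.1f)\n",
              x$condition, x$tau_star, x$per_trial[x$tau_star + 1L]))
  invisible(x)
}
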