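#' Pay-offs in the two-player allocation game
#'
#' The first player (predecessor) explores for `tp` time units and exploits
#' for the remaining `T - tp`; the accumulated technology is transmitted
#' faithfully, so the second player (successor) starts at efficiency
#' `f(tp)`, explores for a further `ts`, and exploits for `T - ts`. The
#' successor's pay-off is `W_s = (T - ts) f(tp + ts)`. In the *unrepaid*
#' condition the predecessor keeps only its own earnings,
#' `W_p = (T - tp) f(tp)`; in the *repaid* condition it additionally
#' receives a bonus equal to the successor's earnings, `W_p = W_{p,u} + W_s`.
#'
#' @param curve A [learning_curve] object.
#' @param tp First player's exploration time, in `[0, T]`.
#' @param ts Second player's exploration time, in `[0, T]` (default 0).
#' @param condition `"unrepaid"` or `"repaid"`.
#' @return A list with components `W_p` and `W_s`.
#' @examples
#' lc <- learning_curve(function(t) 1 + 2 * t, T = 1)
#' evaluate_payoffs(lc, tp = 0.25, condition = "unrepaid")$W_p  # 1.125
#' @export
evaluate_payoffs <- function(curve, tp, ts = 0,
                             condition = c("unrepaid", "repaid")) {
  condition <- match.arg(condition)
  stopifnot(inherits(curve, "learning_curve"))
  T <- curve$T
  if (any(tp < 0 | tp > T)) stop("tp must lie in [0, T]", call. = FALSE)
  if (any(ts < 0 | ts > T)) stop("ts must lie in [0, T]", call. = FALSE)
  W_s <- (T - ts) * curve$f(tp + ts)
  W_pu <- (T - tp) * curve$f(tp)
  W_p <- if (condition == "repaid") W_pu + W_s else W_pu
  list(W_p = W_p, W_s = W_s)
}

# Marginal-balance function whose root is the optimal switching time:
# (H - t) f'(t) - f(t).  Written in product form so that curves with
# f(0) = 0 (e.g. f = t^2) need no special casing.
.switch_root_fn <- function(curve, H) {
  function(t) (H - t) * curve$f_prime(t) - curve$f(t)
}

# Locate the unique sign change of fn on [0, H]: scan a grid for the last
# point with fn > 0, then bisect.  Under log-concavity the marginal benefit
# f'/f is non-increasing and the marginal cost 1/(H - t) strictly
# increasing, so fn changes sign at most once and bisection is safe.
.solve_switch_time <- function(fn, H, scan_points = 1001L, tol = 1e-9) {
  tt <- seq(0, H, length.out = scan_points)
  hv <- fn(tt)
  pos <- which(hv > 0)
  if (!length(pos)) return(0)             # marginal cost dominates from the start
  i <- pos[length(pos)]
  if (i == scan_points) return(H)         # cannot happen for f(H) > 0; guard anyway
  lo <- tt[i]; hi <- tt[i + 1L]
  while (hi - lo > tol * H) {
    mid <- (lo + hi) / 2
    if (fn(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.allocation_solution <- function(condition, tp_star, ts_star, W_p, W_s) {
  structure(list(condition = condition, tp_star = tp_star, ts_star = ts_star,
                 W_p = W_p, W_s = W_s),
            class = "allocation_solution")
}

#' Optimal time allocation for the two-player game
#'
#' Solves for the first player's optimal switching time. In the unrepaid
#' condition `tp*` is the unique root in `(0, T)` of
#' `(T - t) f'(t) - f(t) = 0` (the marginal-benefit/marginal-cost balance
#' `f'/f = 1/(T - t)`), or 0 when the marginal cost already dominates at
#' `t = 0`. The repaid condition reduces to the unrepaid problem with the
#' horizon doubled to `2T`: if the resulting switching time `t*` does not
#' exceed `T` the first player stops at `t*` and the second player never
#' explores (`ts* = 0`); otherwise the first player explores for the whole
#' of its time (`tp* = T`) and the second player continues until `t* - T`.
#' The overshoot case `ts* > 0` can occur only for convex curves.
#'
#' @inheritParams evaluate_payoffs
#' @return An `allocation_solution`: list with `condition`, `tp_star`,
#'   `ts_star`, `W_p`, `W_s`.
#' @examples
#' lc <- learning_curve(function(t) 1 + 2 * t, T = 1)
#' solve_allocation(lc, "unrepaid")$tp_star  # 0.25
#' solve_allocation(lc, "repaid")$tp_star    # 0.75
#' @seealso [grid_oracle()] for a brute-force check.
#' @export
solve_allocation <- function(curve, condition = c("unrepaid", "repaid")) {
  condition <- match.arg(condition)
  stopifnot(inherits(curve, "learning_curve"))
  T <- curve$T
  H <- if (condition == "repaid") 2 * T else T
  t_star <- .solve_switch_time(.switch_root_fn(curve, H), H)
  if (t_star <= T) {
    tp_star <- t_star; ts_star <- 0
  } else {
    tp_star <- T; ts_star <- t_star - T
  }
  pay <- evaluate_payoffs(curve, tp_star, ts_star, condition)
  .allocation_solution(condition, tp_star, ts_star, pay$W_p, pay$W_s)
}

#' Brute-force grid maximizer (independent oracle)
#'
#' Exhaustively evaluates the first player's pay-off over a grid of
#' switching times and returns the maximizer, independently of the
#' root-finding solver. For the unrepaid condition the pay-off depends on
#' `tp` alone and a one-dimensional grid is used. For the repaid condition
#' the full two-dimensional pay-off surface over `(tp, ts)` is searched: a
#' coarse pass over the whole square followed by a refinement pass at the
#' requested `step` around the coarse maximizer.
#'
#' @inheritParams evaluate_payoffs
#' @param step Grid spacing for the (final) search.
#' @return An `allocation_solution`.
#' @export
grid_oracle <- function(curve, condition = c("unrepaid", "repaid"),
                        step = 1e-4) {
  condition <- match.arg(condition)
  stopifnot(inherits(curve, "learning_curve"), step > 0)
  T <- curve$T
  if (condition == "unrepaid") {
    tp <- seq(0, T, by = step)
    W <- (T - tp) * curve$f(tp)
    i <- which.max(W)
    pay <- evaluate_payoffs(curve, tp[i], 0, condition)
    return(.allocation_solution(condition, tp[i], 0, pay$W_p, pay$W_s))
  }
  payoff2 <- function(tp, ts) {
    outer(tp, ts, function(a, b) (T - a) * curve$f(a) + (T - b) * curve$f(a + b))
  }
  coarse <- max(step, T / 250)
  tp <- seq(0, T, by = coarse); ts <- seq(0, T, by = coarse)
  W <- payoff2(tp, ts)
  i <- arrayInd(which.max(W), dim(W))
  lo_p <- max(0, tp[i[1]] - 2 * coarse); hi_p <- min(T, tp[i[1]] + 2 * coarse)
  lo_s <- max(0, ts[i[2]] - 2 * coarse); hi_s <- min(T, ts[i[2]] + 2 * coarse)
  tp <- seq(lo_p, hi_p, by = step); ts <- seq(lo_s, hi_s, by = step)
  W <- payoff2(tp, ts)
  i <- arrayInd(which.max(W), dim(W))
  pay <- evaluate_payoffs(curve, tp[i[1]], ts[i[2]], condition)
  .allocation_solution(condition, tp[i[1]], ts[i[2]], pay$W_p, pay$W_s)
}

#' @export
print.allocation_solution <- function(x, ...) {
  cat(sprintf("Allocation (%s): tp* = %.6g, ts* = %.6g, W_p = %.6g, W_s = %.6g\n",
              x$condition, x$tp_star, x$ts_star, x$W_p, x$W_s))
  invisible(x)
}
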