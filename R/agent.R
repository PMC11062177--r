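#' Win-stay/lose-shift agent state
#'
#' The agent carries four memory slots: the score observed in the latest
#' exploitation trial, and one direction sign (+1/-1) per attribute giving
#' the direction in which that attribute will next be modified. Initial
#' directions are drawn independently and uniformly from {-1, +1} (using
#' the global RNG) unless supplied.
#'
#' @param directions Optional named numeric vector of +1/-1 for
#'   `length`, `width`, `thickness`.
#' @return An object of class `agent_state` with elements `last_score`
#'   (NA before the first hunt), `directions`, and `last_modified` (NA
#'   before the first exploration).
#' @export
agent_state <- function(directions = NULL) {
  if (is.null(directions)) {
    directions <- sample(c(-1, 1), 3L, replace = TRUE)
  }
  stopifnot(length(directions) == 3L, all(directions %in% c(-1, 1)))
  structure(list(last_score = NA_integer_,
                 directions = stats::setNames(as.numeric(directions), .attributes),
                 last_modified = NA_character_),
            class = "agent_state")
}

#' Alternating allocation schedule
#'
#' An agent endowed with `T` trials (trial 1 is always exploitation) that
#' commits to `tau` exploration trials explores on trials `2, 4, ..., 2*tau`
#' and exploits on every other trial. Valid schedules satisfy
#' `0 <= 2*tau <= T - 1`.
#'
#' @param tau Integer number of exploration trials.
#' @param T Integer number of trials (default 50).
#' @return An object of class `allocation_schedule`.
#' @examples
#' schedule_actions(allocation_schedule(2, T = 6))
#' @export
allocation_schedule <- function(tau, T = 50L) {
  stopifnot(length(tau) == 1L, length(T) == 1L, T >= 1, tau == round(tau),
            T == round(T))
  if (tau < 0 || 2 * tau > T - 1) {
    stop("tau must satisfy 0 <= 2*tau <= T - 1", call. = FALSE)
  }
  structure(list(tau = as.integer(tau), T = as.integer(T)),
            class = "allocation_schedule")
}

#' Expand a schedule into per-trial actions
#'
#' @param schedule An [allocation_schedule].
#' @return Character vector of length `T` with entries `"explore"` or
#'   `"exploit"`; exactly `tau` explorations, at the even trials up to
#'   `2*tau`.
#' @export
schedule_actions <- function(schedule) {
  stopifnot(inherits(schedule, "allocation_schedule"))
  actions <- rep("exploit", schedule$T)
  if (schedule$tau > 0) {
    actions[seq(2L, 2L * schedule$tau, by = 2L)] <- "explore"
  }
  actions
}

#' One exploration step
#'
#' The agent picks one attribute uniformly at random and moves it `L` units
#' in the memorized direction, clipping to the admissible range `[1, 100]`.
#' The modified attribute is remembered so that the next losing hunt can
#' reverse its direction. A move clipped at the boundary still registers as
#' the last modification; no direction flip happens at the wall itself.
#'
#' @param state An [agent_state].
#' @param design Current design (integer length-3).
#' @param L Step size in attribute units (default 5).
#' @return List with elements `design` (new design) and `state`.
#' @export
explore_step <- function(state, design, L = 5L) {
  stopifnot(inherits(state, "agent_state"))
  .check_design(design)
  attr_i <- sample.int(3L, 1L)
  design[attr_i] <- min(100L, max(1L, design[attr_i] +
                                    L * state$directions[attr_i]))
  state$last_modified <- .attributes[attr_i]
  list(design = stats::setNames(as.integer(design), .attributes), state = state)
}

#' One exploitation (hunting) step
#'
#' The agent hunts with the current design and observes a noisy score. If
#' the score is strictly lower than the score of the previous exploitation
#' trial, the direction of the attribute modified in the latest exploration
#' trial is reversed (lose-shift); otherwise — including exact ties — all
#' directions are kept (win-stay). Directions of unmodified attributes
#' never change. Comparisons always use the observed (noisy) scores, never
#' the latent efficiency: the agent only ever sees displayed scores.
#'
#' @param state An [agent_state].
#' @param design Current design.
#' @param landscape A [fitness_landscape].
#' @return List with elements `score` (integer) and `state`.
#' @export
exploit_step <- function(state, design, landscape) {
  stopifnot(inherits(state, "agent_state"))
  score <- hunt(landscape, design)
  if (!is.na(state$last_score) && score < state$last_score &&
      !is.na(state$last_modified)) {
    state$directions[state$last_modified] <-
      -state$directions[state$last_modified]
  }
  state$last_score <- score
  list(score = score, state = state)
}

#' @export
print.agent_state <- function(x, ...) {
  cat("WSLS agent: last score =", x$last_score,
      " directions =", paste(sprintf("%+d", x$directions), collapse = " "),
      " last modified =", x$last_modified, "\n")
  invisible(x)
}
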