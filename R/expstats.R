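#' Count exploration trials in a trajectory
#'
#' @param x A `trajectory` data frame, or any data frame with an `action`
#'   column containing only `"explore"`/`"exploit"` entries (e.g. the rows
#'   of a trial-log CSV belonging to one participant).
#' @return Integer number of exploration trials (the participant's tau).
#' @export
exploration_count <- function(x) {
  if (!is.data.frame(x) || !"action" %in% names(x)) {
    stop("expected a data frame with an 'action' column", call. = FALSE)
  }
  if (!all(x$action %in% c("explore", "exploit"))) {
    stop("malformed trajectory: actions must be 'explore' or 'exploit'",
         call. = FALSE)
  }
  sum(x$action == "explore")
}

#' Per-participant exploration counts from trial logs
#'
#' @param logs Trial-log data frame (see [write_trial_logs()] for the
#'   column contract).
#' @return Data frame with one row per participant: `participant_id`,
#'   `condition`, `generation`, `tau`.
#' @export
exploration_counts <- function(logs) {
  .check_logs(logs)
  split_by <- interaction(logs$participant_id, logs$generation, drop = TRUE)
  rows <- lapply(split(logs, split_by), function(d) {
    data.frame(participant_id = d$participant_id[1],
               condition = d$condition[1],
               generation = d$generation[1],
               tau = exploration_count(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$generation, out$participant_id), ]
}

#' Welch two-group comparison with Bonferroni-adjusted threshold
#'
#' Welch's unequal-variance t-test (via [stats::t.test()]) plus Cohen's d
#' computed with the classical pooled standard deviation, and the
#' Bonferroni-adjusted significance threshold `alpha = 0.05 /
#' n_comparisons` (0.025 for the two planned condition contrasts).
#'
#' @param a,b Numeric vectors (each of length >= 2; at least one with
#'   non-zero variance).
#' @param n_comparisons Number of planned comparisons in the family.
#' @return An object of class `group_comparison`: list with `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`, `t`, `df` (Welch-Satterthwaite),
#'   `p` (two-sided), `d` (Cohen's d, pooled SD), `alpha`, `significant`.
#' @examples
#' compare_groups(c(10, 20, 30), c(40, 50, 60), n_comparisons = 2)
#' @export
compare_groups <- function(a, b, n_comparisons = 1L) {
  stopifnot(is.numeric(a), is.numeric(b), n_comparisons >= 1)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    stop("undefined statistic: both groups have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  na <- length(a); nb <- length(b)
  s_pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- (mean(a) - mean(b)) / s_pooled
  alpha <- 0.05 / n_comparisons
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = sqrt(va), sd_b = sqrt(vb),
                 n_a = na, n_b = nb,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = d, alpha = alpha,
                 significant = tt$p.value < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("M1 = %.2f (SD %.2f, n %d) vs M2 = %.2f (SD %.2f, n %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("Welch t(%.2f) = %.3f, p = %.4g, d = %.2f (alpha = %.3f: %s)\n",
              x$df, x$t, x$p, x$d, x$alpha,
              if (x$significant) "significant" else "n.s."))
  invisible(x)
}

#' Convert a cumulative score to a payment in JPY
#'
#' The performance-dependent payment is `2 W / 50` rounded up to the
#' nearest 10 yen, plus the 700-yen show-up fee.
#'
#' @param W Cumulative score(s) in calories, non-negative.
#' @return Integer payment(s) in JPY, always >= 700.
#' @examples
#' payment(24912)  # 1700
#' @export
payment <- function(W) {
  if (any(W < 0)) stop("cumulative score W must be non-negative", call. = FALSE)
  as.integer(700 + 10 * ceiling((2 * W / 50) / 10))
}

#' Final (noise-free) efficiency of a participant
#'
#' The efficiency — expected score before noise — of the design held at the
#' last trial; the endpoint summarized when comparing final arrowhead
#' quality between conditions.
#'
#' @param x A `trajectory` (or one participant's log rows) carrying an
#'   `expected_score` column.
#' @return Efficiency in calories.
#' @export
final_efficiency <- function(x) {
  if (!is.data.frame(x) || !"expected_score" %in% names(x)) {
    stop("expected a trajectory with an 'expected_score' column", call. = FALSE)
  }
  x$expected_score[nrow(x)]
}

#' Fraction of participants overshooting the optimum
#'
#' A participant overshoots an attribute when its trajectory crosses the
#' optimal coordinate, i.e. takes values on both sides of it. Reported per
#' condition/generation and attribute; exploratory output on search
#' behaviour, not an inferential statistic.
#'
#' @param logs Trial-log data frame.
#' @param landscape The [fitness_landscape] the logs were generated on.
#' @return Data frame with `condition`, `generation`, `attribute`,
#'   `fraction`.
#' @export
overshoot_fraction <- function(logs, landscape) {
  .check_logs(logs)
  stopifnot(inherits(landscape, "fitness_landscape"))
  split_by <- interaction(logs$participant_id, logs$generation, drop = TRUE)
  per <- lapply(split(logs, split_by), function(d) {
    over <- vapply(.attributes, function(a) {
      x <- d[[a]]; opt <- landscape$optimum[[a]]
      any(x > opt) && any(x < opt)
    }, logical(1))
    data.frame(condition = d$condition[1], generation = d$generation[1],
               attribute = .attributes, overshoot = over,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per)
  out <- stats::aggregate(overshoot ~ condition + generation + attribute,
                          data = all, FUN = mean)
  names(out)[names(out) == "overshoot"] <- "fraction"
  out
}

.log_columns <- c("participant_id", "condition", "generation", "trial",
                  "action", "length", "width", "thickness",
                  "expected_score", "observed_score", "cumulative_score")

.check_logs <- function(logs) {
  if (!is.data.frame(logs) || !all(.log_columns %in% names(logs))) {
    stop("trial logs must contain columns: ",
         paste(.log_columns, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write trial logs
#'
#' The single interchange format between the simulation and the statistics
#' pipeline: a comma-separated, UTF-8, headered CSV with one row per
#' participant-trial and columns `participant_id`, `condition`,
#' `generation`, `trial`, `action`, `length`, `width`, `thickness`,
#' `expected_score`, `observed_score`, `cumulative_score`. Synthetic and
#' (hypothetical) real data flow through identical code.
#'
#' @param logs Trial-log data frame.
#' @param path CSV file path.
#' @return `read_trial_logs()` returns the logs data frame;
#'   `write_trial_logs()` returns `path` invisibly.
#' @export
write_trial_logs <- function(logs, path) {
  .check_logs(logs)
  utils::write.csv(logs[, .log_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(path) {
  logs <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  .check_logs(logs)
  logs
}

#' Default synthetic-cohort configuration
#'
#' Group sizes and per-condition exploration-count distributions for the
#' parametric generator default to the first-generation summary statistics
#' of the behavioural experiment the package models: n = 20 per condition;
#' tau ~ Normal(20.10, 3.51) (asocial), Normal(19.45, 6.42) (unrepaid),
#' Normal(24.60, 5.56) (repaid). The agentic generator instead fixes tau at
#' the rational optima found by simulation (12, 12 and 22).
#'
#' @param mode `"parametric"` or `"agentic"`.
#' @param n Participants per condition group.
#' @return A config list understood by [synth_participants()].
#' @export
default_synth_config <- function(mode = c("parametric", "agentic"), n = 20L) {
  mode <- match.arg(mode)
  groups <- if (mode == "parametric") {
    list(list(condition = "asocial", n = n, tau_mean = 20.10, tau_sd = 3.51),
         list(condition = "unrepaid", n = n, tau_mean = 19.45, tau_sd = 6.42),
         list(condition = "repaid", n = n, tau_mean = 24.60, tau_sd = 5.56))
  } else {
    list(list(condition = "asocial", n = n, tau = 12L),
         list(condition = "unrepaid", n = n, tau = 12L),
         list(condition = "repaid", n = n, tau = 22L))
  }
  list(mode = mode, T = 50L, groups = groups, chain = FALSE,
       gen2 = list(tau_mean = 20.10, tau_sd = 3.51))
}

#' Generate synthetic participant cohorts
#'
#' Stand-in for the (undistributed) human trial logs: synthesizes
#' first-generation cohorts whose exploration counts follow a configured
#' distribution, with full per-trial trajectories simulated by the
#' win-stay/lose-shift agent so that every record is internally consistent
#' (counting its explore rows recovers its tau; efficiencies and scores
#' come from the landscape).
#'
#' In `parametric` mode each participant's tau is drawn from
#' `Normal(tau_mean, tau_sd)`, rounded and clipped to the behaviourally
#' admissible range `[0, T-1]` (only trial 1 is a forced exploitation);
#' participants whose tau exceeds the alternating-family cap
#' `floor((T-1)/2)` alternate as long as possible and then keep exploring
#' through the trailing trials, mirroring the over-exploration observed in
#' transmission-chain experiments. In `agentic` mode tau is fixed per
#' condition (rational-agent behaviour, always within the alternating
#' family); all variation comes from the WSLS dynamics.
#' With `config$chain = TRUE`, each social-condition participant also gets
#' a second-generation partner (tau from `config$gen2`) whose initial
#' design is the partner's final design.
#'
#' @param config Config list as produced by [default_synth_config()].
#' @param landscape A [fitness_landscape] (default [default_landscape()]).
#' @param seed Optional seed for reproducible cohorts.
#' @return Trial-log data frame (see [write_trial_logs()]); a
#'   per-participant summary (`participant_id`, `condition`, `generation`,
#'   `tau`, `W`, `payment`) is attached as attribute `"participants"`.
#' @examples
#' logs <- synth_participants(default_synth_config(n = 3), seed = 1)
#' attr(logs, "participants")
#' @export
synth_participants <- function(config = default_synth_config(),
                               landscape = default_landscape(),
                               seed = NULL) {
  .check_synth_config(config)
  if (!is.null(seed)) set.seed(seed)
  T <- config$T
  tau_cap <- T - 1L
  logs <- list(); summ <- list(); k <- 0L
  for (grp in config$groups) {
    for (j in seq_len(grp$n)) {
      k <- k + 1L
      tau <- if (config$mode == "parametric") {
        min(tau_cap, max(0L, as.integer(round(
          stats::rnorm(1, grp$tau_mean, grp$tau_sd)))))
      } else {
        as.integer(grp$tau)
      }
      pid <- sprintf("%s_%02d", grp$condition, j)
      sched <- if (config$mode == "agentic") {
        allocation_schedule(tau, T)
      } else {
        .tau_actions(tau, T)
      }
      tr <- run_generation(sched, landscape)
      logs[[length(logs) + 1L]] <- .tag_logs(tr, pid, grp$condition, 1L)
      summ[[length(summ) + 1L]] <-
        data.frame(participant_id = pid, condition = grp$condition,
                   generation = 1L, tau = tau, W = attr(tr, "W"),
                   payment = payment(attr(tr, "W")),
                   stringsAsFactors = FALSE)
      if (isTRUE(config$chain) && grp$condition != "asocial") {
        tau2 <- min(tau_cap, max(0L, as.integer(round(
          stats::rnorm(1, config$gen2$tau_mean, config$gen2$tau_sd)))))
        final <- as.integer(tr[T, c("length", "width", "thickness")])
        tr2 <- run_generation(.tau_actions(tau2, T), landscape,
                              initial_design = final)
        logs[[length(logs) + 1L]] <- .tag_logs(tr2, pid, grp$condition, 2L)
        summ[[length(summ) + 1L]] <-
          data.frame(participant_id = pid, condition = grp$condition,
                     generation = 2L, tau = tau2, W = attr(tr2, "W"),
                     payment = payment(attr(tr2, "W")),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  attr(out, "participants") <- {
    s <- do.call(rbind, summ); rownames(s) <- NULL; s
  }
  out
}

.tag_logs <- function(trajectory, pid, condition, generation) {
  cbind(data.frame(participant_id = pid, condition = condition,
                   generation = generation, stringsAsFactors = FALSE),
        as.data.frame(trajectory))
}

.check_synth_config <- function(config) {
  if (!is.list(config) || !all(c("mode", "T", "groups") %in% names(config))) {
    stop("synth config needs elements: mode, T, groups", call. = FALSE)
  }
  if (!config$mode %in% c("parametric", "agentic")) {
    stop("synth mode must be 'parametric' or 'agentic'", call. = FALSE)
  }
  for (grp in config$groups) {
    if (is.null(grp$condition) ||
        !grp$condition %in% c("asocial", "unrepaid", "repaid")) {
      stop("each group needs a condition in {asocial, unrepaid, repaid}",
           call. = FALSE)
    }
    if (is.null(grp$n) || grp$n < 1) {
      stop("each group needs a positive size n", call. = FALSE)
    }
    if (config$mode == "parametric" &&
        (is.null(grp$tau_mean) || is.null(grp$tau_sd) || grp$tau_sd < 0)) {
      stop("parametric groups need tau_mean and non-negative tau_sd",
           call. = FALSE)
    }
    if (config$mode == "agentic" && is.null(grp$tau)) {
      stop("agentic groups need a fixed tau", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run the planned condition contrasts on trial logs
#'
#' Compares first-generation exploration counts between conditions with
#' Welch t-tests, Bonferroni-adjusting the significance threshold for the
#' number of planned contrasts.
#'
#' @param logs Trial-log data frame.
#' @param comparisons Character vector of contrasts `"groupA:groupB"`
#'   (default: the two planned contrasts against the asocial control).
#' @return Named list of [compare_groups()] results.
#' @export
analyze_exploration <- function(logs,
                                comparisons = c("repaid:asocial",
                                                "unrepaid:asocial")) {
  counts <- exploration_counts(logs)
  counts <- counts[counts$generation == 1L, ]
  out <- lapply(comparisons, function(cmp) {
    gg <- strsplit(cmp, ":", fixed = TRUE)[[1]]
    if (length(gg) != 2L) stop("comparison must look like 'a:b'", call. = FALSE)
    a <- counts$tau[counts$condition == gg[1]]
    b <- counts$tau[counts$condition == gg[2]]
    if (!length(a) || !length(b)) {
      stop("no participants for comparison ", cmp, call. = FALSE)
    }
    compare_groups(a, b, n_comparisons = length(comparisons))
  })
  names(out) <- comparisons
  out
}
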