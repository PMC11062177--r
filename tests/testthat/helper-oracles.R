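# Shared fixtures and independent oracles, built in code at test time.

# --- battery of valid learning curves -------------------------------------
# Linear and concave members have ts* = 0 in both conditions; convex but
# log-concave members (exp, powers > 1) may push the repaid optimum past T.
curve_battery <- function() {
  entries <- list()
  add <- function(f, T, fp = NULL, convex = FALSE, name = "") {
    entries[[length(entries) + 1L]] <<-
      list(curve = learning_curve(f, T = T, f_prime = fp), convex = convex,
           name = name)
  }
  # linear a + b t
  for (ab in list(c(1, 2), c(1, 0.5), c(2, 1), c(0.5, 3), c(3, 0.25))) {
    local({
      a <- ab[1]; b <- ab[2]
      add(function(t) a + b * t, T = 1,
          fp = function(t) rep(b, length(t)), name = sprintf("lin %g+%gt", a, b))
    })
  }
  add(function(t) 1 + 2 * t, T = 2, fp = function(t) rep(2, length(t)),
      name = "lin T=2")
  add(function(t) 0.2 + t, T = 5, fp = function(t) rep(1, length(t)),
      name = "lin T=5")
  # concave
  add(function(t) sqrt(t + 0.5), T = 1,
      fp = function(t) 0.5 / sqrt(t + 0.5), name = "sqrt")
  add(function(t) log(2 + t), T = 1, fp = function(t) 1 / (2 + t), name = "log")
  add(function(t) (t + 1)^0.7, T = 1,
      fp = function(t) 0.7 * (t + 1)^(-0.3), name = "pow0.7")
  add(function(t) 2 - exp(-t), T = 1, fp = function(t) exp(-t), name = "sat")
  add(function(t) sqrt(t + 0.1), T = 2,
      fp = function(t) 0.5 / sqrt(t + 0.1), name = "sqrt T=2")
  add(function(t) 1 + log(1 + 3 * t), T = 2,
      fp = function(t) 3 / (1 + 3 * t), name = "log T=2")
  # convex, log-concave
  for (a in c(0.5, 1.5, 2)) {
    local({
      aa <- a
      add(function(t) exp(aa * t), T = 1, fp = function(t) aa * exp(aa * t),
          convex = TRUE, name = sprintf("exp %g", aa))
    })
  }
  for (b in c(1.5, 2, 3)) {
    local({
      bb <- b
      add(function(t) t^bb, T = 1, fp = function(t) bb * t^(bb - 1),
          convex = TRUE, name = sprintf("t^%g", bb))
    })
  }
  add(function(t) (0.5 + t)^2, T = 1, fp = function(t) 2 * (0.5 + t),
      convex = TRUE, name = "(.5+t)^2")
  add(function(t) exp(0.8 * t), T = 2, fp = function(t) 0.8 * exp(0.8 * t),
      convex = TRUE, name = "exp T=2")
  add(function(t) t^2, T = 0.5, fp = function(t) 2 * t,
      convex = TRUE, name = "t^2 T=.5")
  entries
}

# --- hand-coded Welch t oracle --------------------------------------------
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  sea <- va / na; seb <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(sea + seb)
  df <- (sea + seb)^2 / (sea^2 / (na - 1) + seb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  d <- (mean(a) - mean(b)) /
    sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  list(t = t, df = df, p = p, d = d)
}

# --- toy landscapes --------------------------------------------------------
toy_landscape <- function(noise_sd = 0) {
  fitness_landscape(optimum = c(60, 45, 55), weights = c(0.5, 0.3, 0.2),
                    peak = 800, noise_sd = noise_sd,
                    initial_design = c(50, 50, 50))
}

# A landscape whose expected score at its own initial design is an exact
# chosen value; used for forcing win/lose/tie comparisons without noise.
flat_landscape <- function(score) {
  fitness_landscape(optimum = c(50, 50, 50), weights = rep(1e-9, 3),
                    peak = score, noise_sd = 0,
                    initial_design = c(50, 50, 50))
}

# --- exact enumeration oracle for g(tau) on a tiny zero-noise instance ----
# Enumerates every equally likely path of the win-stay/lose-shift process
# (8 initial direction combinations x 3^tau_max attribute-choice sequences)
# for T trials with noise_sd = 0, and returns the exact expected efficiency
# after each exploration count.  Scalar re-implementation, independent of
# the package's vectorised ensemble code.
enumerate_g <- function(landscape, T = 10L, L = 5L) {
  stopifnot(landscape$noise_sd == 0)
  tau_max <- (T - 1L) %/% 2L
  eff1 <- function(d) {
    max(0, landscape$peak - sum(landscape$weights * (d - landscape$optimum)^2))
  }
  dirs_grid <- expand.grid(d1 = c(-1, 1), d2 = c(-1, 1), d3 = c(-1, 1))
  attr_grid <- do.call(expand.grid, rep(list(1:3), tau_max))
  acc <- numeric(tau_max + 1L)
  n_paths <- nrow(dirs_grid) * nrow(attr_grid)
  for (i in seq_len(nrow(dirs_grid))) {
    for (j in seq_len(nrow(attr_grid))) {
      dir <- as.numeric(dirs_grid[i, ])
      attrs <- as.integer(attr_grid[j, ])
      design <- as.numeric(landscape$initial_design)
      last_score <- NA_real_; last_mod <- NA_integer_
      tau <- 0L
      path_eff <- numeric(tau_max + 1L)
      path_eff[1L] <- eff1(design)
      for (trial in seq_len(T)) {
        if (trial %% 2L == 0L && tau < tau_max) {
          tau <- tau + 1L
          a <- attrs[tau]
          design[a] <- min(100, max(1, design[a] + L * dir[a]))
          last_mod <- a
          path_eff[tau + 1L] <- eff1(design)
        } else {
          sc <- min(1000, max(0, round(eff1(design))))
          if (!is.na(last_score) && sc < last_score && !is.na(last_mod)) {
            dir[last_mod] <- -dir[last_mod]
          }
          last_score <- sc
        }
      }
      acc <- acc + path_eff
    }
  }
  acc / n_paths
}

# Random small landscapes for ordering properties (seeded by caller).
random_landscape <- function() {
  repeat {
    off <- sample(10:55, 3, replace = TRUE)
    sgn <- sample(c(-1, 1), 3, replace = TRUE)
    init <- sample(25:75, 3, replace = TRUE)
    opt <- init + sgn * off
    if (any(opt < 1 | opt > 100)) next
    w <- exp(stats::runif(3, log(0.03), log(0.6)))
    if (1000 - sum(w * off^2) < 20) next
    return(fitness_landscape(optimum = opt, weights = w, peak = 1000,
                             noise_sd = 5, initial_design = init))
  }
}
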