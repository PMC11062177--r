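#' Learning-curve specification
#'
#' Bundles an efficiency function `f(t)` (pay-off earned per unit time of
#' exploitation after `t` units of exploration) with its time horizon `T`
#' and, optionally, its derivative. The continuous allocation model assumes
#' `f(t) >= 0`, `f'(t) > 0` and that `log f(t)` is concave on `[0, 2T]`;
#' these conditions are checked on a dense grid at construction time. The
#' class covers all increasing concave curves as well as log-concave convex
#' ones such as `exp(a t)` or `t^b`.
#'
#' @param f Function of one argument: exploration time to efficiency. Must
#'   accept vector input.
#' @param T Positive scalar time horizon available to each player.
#' @param f_prime Optional derivative of `f`. When `NULL`, central finite
#'   differences with step `1e-6 * (1 + |t|)` are used.
#' @param validate Logical; run the grid validation (default `TRUE`).
#' @param on_violation `"error"` (default) to reject invalid curves,
#'   `"warning"` to downgrade violations to a warning.
#' @param grid_points Number of validation grid points over `[0, 2T]`.
#'
#' @return An object of class `learning_curve` with elements `f`, `f_prime`
#'   (always callable) and `T`.
#' @examples
#' lc <- learning_curve(function(t) 1 + 2 * t, T = 1)
#' lc$f(0.25)
#' @export
learning_curve <- function(f, T, f_prime = NULL, validate = TRUE,
                           on_violation = c("error", "warning"),
                           grid_points = 1001L) {
  on_violation <- match.arg(on_violation)
  stopifnot(is.function(f), is.numeric(T), length(T) == 1L, T > 0)
  if (is.null(f_prime)) {
    f_prime <- function(t) {
      h <- 1e-6 * (1 + abs(t))
      (f(t + h) - f(t - h)) / (2 * h)
    }
  }
  obj <- structure(list(f = f, f_prime = f_prime, T = T),
                   class = "learning_curve")
  if (validate) {
    validate_learning_curve(obj, on_violation = on_violation,
                            grid_points = grid_points)
  }
  obj
}

#' Validate a learning curve on a grid
#'
#' Checks, on an evenly spaced grid over `[0, 2T]`, that `f(t) >= 0`, that
#' `f'(t) > 0`, and that the second difference of `log f(t)` never exceeds a
#' small positive tolerance (log-concavity). Grid points with
#' `f(t) < 1e-30` are skipped in the log-concavity check so that curves
#' vanishing at isolated points (e.g. `f(t) = t^2`) remain admissible.
#'
#' @param curve A `learning_curve` object.
#' @param tol Tolerance on the second difference of `log f` (default `1e-8`).
#' @param on_violation `"error"` or `"warning"`.
#' @param grid_points Number of grid points.
#' @return Invisibly `TRUE` on success. A violation raises a condition whose
#'   message lists the offending grid points.
#' @export
validate_learning_curve <- function(curve, tol = 1e-8,
                                    on_violation = c("error", "warning"),
                                    grid_points = 1001L) {
  on_violation <- match.arg(on_violation)
  stopifnot(inherits(curve, "learning_curve"))
  tt <- seq(0, 2 * curve$T, length.out = grid_points)
  fv <- curve$f(tt)
  dv <- curve$f_prime(tt)
  bad <- character(0)
  if (any(neg <- fv < 0)) {
    bad <- c(bad, sprintf("f(t) < 0 at t = %s",
                          paste(signif(tt[neg][seq_len(min(5, sum(neg)))], 4),
                                collapse = ", ")))
  }
  # strict monotonicity is only required where f is bounded away from its
  # isolated zeros (so f(t) = t^2, with f'(0) = 0 exactly at f = 0, passes)
  if (any(dec <- dv <= 0 & fv >= 1e-30)) {
    bad <- c(bad, sprintf("f'(t) <= 0 at t = %s",
                          paste(signif(tt[dec][seq_len(min(5, sum(dec)))], 4),
                                collapse = ", ")))
  }
  keep <- fv >= 1e-30
  lf <- rep(NA_real_, length(tt))
  lf[keep] <- log(fv[keep])
  d2 <- diff(lf, differences = 2)  # NA wherever a skipped point is involved
  viol <- which(!is.na(d2) & d2 > tol)
  if (length(viol)) {
    bad <- c(bad, sprintf("log f not concave near t = %s",
                          paste(signif(tt[viol + 1L][seq_len(min(5, length(viol)))], 4),
                                collapse = ", ")))
  }
  if (length(bad)) {
    msg <- paste0("invalid learning curve:\n  ", paste(bad, collapse = "\n  "))
    if (on_violation == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a learning curve from a preset string
#'
#' Presets: `"linear:a,b"` for `a + b t`, `"power:b"` for `t^b` and
#' `"exp:a"` for `exp(a t)`.
#'
#' @param preset Preset string.
#' @param T Time horizon.
#' @inheritParams learning_curve
#' @return A `learning_curve` object.
#' @examples
#' curve_preset("linear:1,2", T = 1)
#' @export
curve_preset <- function(preset, T, validate = TRUE) {
  stopifnot(is.character(preset), length(preset) == 1L)
  parts <- strsplit(preset, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("preset must look like 'linear:a,b', 'power:b' or 'exp:a'", call. = FALSE)
  }
  args <- suppressWarnings(as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
  if (anyNA(args)) stop("could not parse numeric preset parameters", call. = FALSE)
  switch(parts[1],
    linear = {
      if (length(args) != 2L) stop("linear preset needs two parameters a,b", call. = FALSE)
      a <- args[1]; b <- args[2]
      learning_curve(function(t) a + b * t, T = T,
                     f_prime = function(t) rep(b, length(t)), validate = validate)
    },
    power = {
      if (length(args) != 1L) stop("power preset needs one parameter b", call. = FALSE)
      b <- args[1]
      learning_curve(function(t) t^b, T = T,
                     f_prime = function(t) b * t^(b - 1), validate = validate)
    },
    exp = {
      if (length(args) != 1L) stop("exp preset needs one parameter a", call. = FALSE)
      a <- args[1]
      learning_curve(function(t) exp(a * t), T = T,
                     f_prime = function(t) a * exp(a * t), validate = validate)
    },
    stop("unknown preset '", parts[1], "'", call. = FALSE)
  )
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("Learning curve: f(0) =", signif(x$f(0), 4),
      " f(T) =", signif(x$f(x$T), 4), " T =", x$T, "\n")
  invisible(x)
}
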