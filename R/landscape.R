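#' Arrowhead design
#'
#' A virtual arrowhead is described by three integer attributes — length,
#' width and thickness — each restricted to `[1, 100]`.
#'
#' @param length,width,thickness Integer attribute values in `[1, 100]`.
#' @return A named integer vector of class `arrowhead_design`.
#' @examples
#' arrowhead_design(30, 40, 35)
#' @export
arrowhead_design <- function(length, width, thickness) {
  d <- c(length = length, width = width, thickness = thickness)
  .check_design(d)
  structure(as.integer(round(d)),
            names = c("length", "width", "thickness"),
            class = "arrowhead_design")
}

.attributes <- c("length", "width", "thickness")

.check_design <- function(d) {
  if (length(d) != 3L || anyNA(d)) {
    stop("a design needs three non-missing attribute values", call. = FALSE)
  }
  if (any(d != round(d))) {
    stop("attribute values must be integers", call. = FALSE)
  }
  if (any(d < 1 | d > 100)) {
    stop("attribute values must lie in [1, 100]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Unimodal quadratic fitness landscape
#'
#' The expected score (in calories) of a design is a quadratic bowl around a
#' single optimum: `peak - sum_i w_i (x_i - opt_i)^2`, floored at 0, so that
#' scores always fall in `[0, peak]` with `peak <= 1000`. Hunting returns
#' the expected score plus Gaussian noise (`noise_sd`, default 5 calories),
#' rounded and clamped to `[0, 1000]`.
#'
#' @param optimum Numeric length-3: the optimal attribute values (may be
#'   non-integer).
#' @param weights Positive numeric length-3: quadratic penalty per attribute.
#' @param peak Maximum expected score; at most 1000.
#' @param noise_sd Standard deviation of the hunting noise, calories.
#' @param initial_design Integer length-3: the design all first-generation
#'   individuals start from.
#' @return An object of class `fitness_landscape`.
#' @examples
#' fitness_landscape(optimum = c(85, 95, 90), weights = rep(0.07, 3),
#'                   peak = 1000, noise_sd = 5,
#'                   initial_design = c(30, 40, 35))
#' @export
fitness_landscape <- function(optimum, weights, peak = 1000, noise_sd = 5,
                              initial_design) {
  stopifnot(length(optimum) == 3L, length(weights) == 3L,
            all(weights > 0), length(peak) == 1L, peak > 0, peak <= 1000,
            length(noise_sd) == 1L, noise_sd >= 0)
  .check_design(initial_design)
  structure(list(optimum = stats::setNames(as.numeric(optimum), .attributes),
                 weights = stats::setNames(as.numeric(weights), .attributes),
                 peak = as.numeric(peak),
                 noise_sd = as.numeric(noise_sd),
                 initial_design = stats::setNames(as.integer(initial_design),
                                                  .attributes)),
            class = "fitness_landscape")
}

#' Noise-free expected score (efficiency) of a design
#'
#' @param landscape A [fitness_landscape].
#' @param design Integer length-3 design, or an `n x 3` matrix of designs
#'   (one per row).
#' @return Expected score(s) in `[0, peak]` calories; the "efficiency" used
#'   throughout the analysis of trajectories.
#' @examples
#' ls <- default_landscape()
#' expected_score(ls, ls$initial_design)
#' @export
expected_score <- function(landscape, design) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  if (is.matrix(design)) {
    if (ncol(design) != 3L) stop("design matrix needs 3 columns", call. = FALSE)
    apply(design, 1L, .check_design)
    return(.efficiency(landscape, design))
  }
  .check_design(design)
  .efficiency(landscape, matrix(design, nrow = 1L))[1L]
}

# Vectorised core, no validation: rows of `mat` are designs.
.efficiency <- function(landscape, mat) {
  pen <- (mat[, 1L] - landscape$optimum[1L])^2 * landscape$weights[1L] +
         (mat[, 2L] - landscape$optimum[2L])^2 * landscape$weights[2L] +
         (mat[, 3L] - landscape$optimum[3L])^2 * landscape$weights[3L]
  pmax(0, landscape$peak - pen)
}

#' Go hunting: noisy displayed score
#'
#' Draws the score shown to a participant after one exploitation trial:
#' `round(expected_score + eps)` with `eps ~ N(0, noise_sd^2)`, clamped to
#' `[0, 1000]`. Uses R's global random number stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @inheritParams expected_score
#' @return An integer score in `[0, 1000]`.
#' @export
hunt <- function(landscape, design) {
  mu <- expected_score(landscape, design)
  .clamp_score(mu + stats::rnorm(length(mu), 0, landscape$noise_sd))
}

.clamp_score <- function(x) as.integer(pmin(1000, pmax(0, round(x))))

#' Read / write a landscape configuration file
#'
#' The configuration is a small YAML key-value file with blocks `optimum`,
#' `weights` and `initial_design` (keys `length`, `width`, `thickness`) and
#' scalars `peak` and `noise_sd`.
#'
#' @param path File path.
#' @return `read_landscape_config()` returns a [fitness_landscape];
#'   `write_landscape_config()` returns `path` invisibly.
#' @export
read_landscape_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("optimum", "weights", "peak", "noise_sd", "initial_design")
  if (!all(need %in% names(cfg))) {
    stop("landscape config must define: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pick <- function(block) unlist(block)[.attributes]
  fitness_landscape(optimum = pick(cfg$optimum),
                    weights = pick(cfg$weights),
                    peak = cfg$peak,
                    noise_sd = cfg$noise_sd,
                    initial_design = pick(cfg$initial_design))
}

#' @rdname read_landscape_config
#' @param landscape A [fitness_landscape] to serialize.
#' @export
write_landscape_config <- function(landscape, path) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  cfg <- list(optimum = as.list(landscape$optimum),
              weights = as.list(landscape$weights),
              peak = landscape$peak,
              noise_sd = landscape$noise_sd,
              initial_design = as.list(landscape$initial_design))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' The calibrated default landscape
#'
#' Loads the package's default virtual-arrowhead landscape, calibrated (see
#' `scripts/calibrate_landscape.R` in the source tree and the methods
#' vignette) so that the 10,000-agent learning-curve analysis places the
#' optimal number of exploration trials at 12 in the unrepaid/asocial
#' condition and 22 in the repaid condition for `T = 50` trials.
#'
#' @return A [fitness_landscape].
#' @export
default_landscape <- function() {
  read_landscape_config(system.file("extdata", "default_landscape.yaml",
                                    package = "exploregen", mustWork = TRUE))
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("Quadratic fitness landscape\n")
  cat("  optimum       :", paste(signif(x$optimum, 4), collapse = ", "), "\n")
  cat("  weights       :", paste(signif(x$weights, 4), collapse = ", "), "\n")
  cat("  peak / noise  :", x$peak, "/", x$noise_sd, "\n")
  cat("  initial design:", paste(x$initial_design, collapse = ", "), "\n")
  invisible(x)
}
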