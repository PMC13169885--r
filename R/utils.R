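#' @keywords internal
"_PACKAGE"

# Duration grid used by the synthesiser so that segment boundaries land on
# envelope hop boundaries (5 ms at the default analysis settings).
.grid_ms <- 5

#' Distribution specification for generator parameters
#'
#' A small declarative container for the per-group parameter distributions
#' used by the synthetic cohort generator. Three families are supported:
#' `"point"` (a degenerate point mass at `mean`), `"normal"` (Gaussian with
#' `mean` and `sd`, clamped to `[min, max]` when bounds are given), and
#' `"uniform"` (uniform on `[min, max]`).
#'
#' @param dist One of `"point"`, `"normal"`, `"uniform"`.
#' @param mean Location (point mass value or Gaussian mean).
#' @param sd Standard deviation (normal only).
#' @param min,max Optional hard bounds; normal draws are clamped to them.
#' @return An object of class `vm_dist`.
#' @examples
#' draw_dist(dist_spec("point", 0.3), 5)
#' @export
dist_spec <- function(dist = c("point", "normal", "uniform"),
                      mean = NULL, sd = NULL, min = -Inf, max = Inf) {
  dist <- match.arg(dist)
  if (dist %in% c("point", "normal") && (is.null(mean) || !is.finite(mean)))
    stop("dist_spec: 'mean' must be a finite number for '", dist, "'")
  if (dist == "normal" && (is.null(sd) || !is.finite(sd) || sd < 0))
    stop("dist_spec: 'sd' must be a finite non-negative number for 'normal'")
  if (dist == "uniform" && (!is.finite(min) || !is.finite(max) || min > max))
    stop("dist_spec: 'uniform' needs finite min <= max")
  structure(list(dist = dist, mean = mean, sd = sd, min = min, max = max),
            class = "vm_dist")
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "vm_dist"))
  x <- switch(spec$dist,
    point   = rep(spec$mean, n),
    normal  = stats::rnorm(n, spec$mean, spec$sd),
    uniform = stats::runif(n, spec$min, spec$max)
  )
  pmin(pmax(x, spec$min), spec$max)
}

# round a duration in seconds to the synthesiser grid
round_to_grid_s <- function(x, grid_ms = .grid_ms) {
  round(x * 1000 / grid_ms) * grid_ms / 1000
}

# check a probability vector / table
check_probs <- function(p, name, tol = 1e-9, must_sum = FALSE) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("configuration error: '", name, "' must contain probabilities in [0, 1]")
  if (must_sum && abs(sum(p) - 1) > tol)
    stop("configuration error: '", name, "' must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

# derive a stream of independent sub-seeds from one root seed
split_seed <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
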