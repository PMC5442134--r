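#' Game parameters for the common-pool resource game
#'
#' Bundles the environment constants of the harvesting game: a resource with
#' logistic regrowth is exploited by a group whose cumulative effort enters a
#' Cobb-Douglas production function. The defaults are the reference
#' parameterisation used throughout the package's experiments.
#'
#' @param N_max Carrying capacity of the resource (stock units, > 0).
#' @param r_g Intrinsic replenishment rate per round (>= 0).
#' @param alpha Cobb-Douglas effort elasticity, in \[0, 1\]. Low values make
#'   the harvest depend mostly on the stock, high values mostly on effort.
#' @param beta Cobb-Douglas scale factor, in \[0, 1\].
#' @param X_min Lower bound on the group's cumulative effort (> 0;
#'   participation is not voluntary, some effort is always invested).
#' @param X_max Upper bound on the group's cumulative effort (>= `X_min`).
#' @param c Cost per unit of effort invested (currency per effort unit, >= 0).
#'
#' @return An object of class `cprg_params`: a named list with the seven
#'   constants, validated.
#' @examples
#' p <- cprg_params()
#' p$N_max
#' cprg_params(c = 0.2) # low-cost variant
#' @export
cprg_params <- function(N_max = 1000, r_g = 0.5, alpha = 0.35, beta = 0.4,
                        X_min = 100, X_max = 500, c = 0.5) {
  p <- list(N_max = N_max, r_g = r_g, alpha = alpha, beta = beta,
            X_min = X_min, X_max = X_max, c = c)
  validate_params(p)
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (k in names(p)) {
    if (!num1(p[[k]])) {
      stop("parameter `", k, "` must be a single finite number", call. = FALSE)
    }
  }
  if (p$N_max <= 0) stop("`N_max` must be > 0", call. = FALSE)
  if (p$r_g < 0) stop("`r_g` must be >= 0", call. = FALSE)
  if (p$alpha < 0 || p$alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (p$beta < 0 || p$beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  if (p$X_min <= 0) stop("`X_min` must be > 0", call. = FALSE)
  if (p$X_max < p$X_min) stop("`X_max` must be >= `X_min`", call. = FALSE)
  if (p$c < 0) stop("`c` must be >= 0", call. = FALSE)
  structure(p, class = "cprg_params")
}

#' @export
print.cprg_params <- function(x, ...) {
  cat("<cprg_params>\n")
  cat(sprintf("  N_max = %g, r_g = %g, alpha = %g, beta = %g\n",
              x$N_max, x$r_g, x$alpha, x$beta))
  cat(sprintf("  X_min = %g, X_max = %g, c = %g\n", x$X_min, x$X_max, x$c))
  invisible(x)
}

as_cprg_params <- function(x) {
  if (inherits(x, "cprg_params")) return(x)
  if (is.list(x)) return(do.call(cprg_params, x))
  stop("cannot interpret `params`; use cprg_params()", call. = FALSE)
}
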