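#' Survival-function parameters
#'
#' Bundles the scaling parameters of the gamete and zygote survival
#' functions. Two variants are supported. The `"levitan"` variant uses the
#' sigmoidal survival function `exp(-scale/size)` for both gametes
#' (scale `alpha`) and zygotes (scale `beta`). The `"threshold"` variant
#' keeps the sigmoidal zygote function but replaces gamete survival with a
#' step: gametes below the viability threshold `delta` die, gametes at or
#' above it survive with probability one.
#'
#' @param alpha Volume scale of gamete survival (um^3, > 0). Required for the
#'   levitan variant; ignored (and may be `NA`) for the threshold variant.
#' @param beta Volume scale of zygote survival (um^3, > 0).
#' @param delta Threshold gamete-viability volume (um^3, >= 0). Only used by
#'   the threshold variant.
#' @param variant Either `"levitan"` or `"threshold"`.
#' @return An object of class `"survival_params"`: a list with fields
#'   `alpha`, `beta`, `delta` and `variant`.
#' @examples
#' survival_params(alpha = 80, beta = 10380)
#' survival_params(beta = 16, delta = 1, variant = "threshold")
#' @export
survival_params <- function(alpha = NA_real_, beta, delta = 0,
                            variant = c("levitan", "threshold")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0)
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  if (variant == "levitan") {
    if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
        alpha <= 0) {
      stop("levitan variant requires a finite alpha > 0", call. = FALSE)
    }
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         delta = as.numeric(delta), variant = variant),
    class = "survival_params"
  )
}

#' @export
print.survival_params <- function(x, ...) {
  cat("Survival parameters (", x$variant, " variant)\n", sep = "")
  cat("  alpha:", x$alpha, " beta:", x$beta, " delta:", x$delta, "\n")
  invisible(x)
}

as_survival_params <- function(params) {
  if (!inherits(params, "survival_params")) {
    stop("`params` must be created with survival_params()", call. = FALSE)
  }
  params
}

check_budget <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0) {
    stop("gamete budget M must be a single positive volume", call. = FALSE)
  }
  as.numeric(M)
}

#' Gamete survival probability
#'
#' Probability that a gamete of volume `m` survives to fertilization.
#' Levitan variant: `exp(-alpha/m)`. Threshold variant: 0 below `delta`,
#' 1 at or above it (the boundary is viable).
#'
#' @param m Gamete volume(s), um^3, > 0. Vectorized.
#' @param params A [survival_params()] object.
#' @return Survival probabilities in `[0, 1]`.
#' @examples
#' gamete_survival(80, survival_params(alpha = 80, beta = 1))
#' @export
gamete_survival <- function(m, params) {
  params <- as_survival_params(params)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("gamete volume m must be positive", call. = FALSE)
  }
  if (params$variant == "levitan") {
    exp(-params$alpha / m)
  } else {
    as.numeric(m >= params$delta)
  }
}

#' Zygote survival probability
#'
#' Probability that a zygote of volume `S` survives, `exp(-beta/S)` under
#' both variants. The function is sigmoidal: accelerating up to `S = beta/2`
#' and decelerating above, with asymptote one.
#'
#' @param S Zygote volume(s), um^3, > 0. Vectorized.
#' @param params A [survival_params()] object.
#' @return Survival probabilities in `[0, 1]`.
#' @export
zygote_survival <- function(S, params) {
  params <- as_survival_params(params)
  if (any(!is.finite(S)) || any(S <= 0)) {
    stop("zygote volume S must be positive", call. = FALSE)
  }
  exp(-params$beta / S)
}

#' Fitness of a rare gamete-size mutant
#'
#' Fitness of a haploid mutant producing gametes of volume `m1` whose
#' gametes fuse with resident gametes of volume `m2`:
#' `(M/m1) * g(m1) * f(m1 + m2)`, the product of fertility (number of
#' gametes cut from the fixed budget `M`), gamete survival and zygote
#' survival.
#'
#' @param m1 Mutant gamete volume (um^3, > 0). Vectorized.
#' @param m2 Resident (partner) gamete volume (um^3, > 0).
#' @param M Gamete budget: total volume available for gamete production per
#'   reproductive cell (um^3, > 0).
#' @param params A [survival_params()] object.
#' @return Fitness (dimensionless, >= 0); linear in `M`.
#' @examples
#' p <- survival_params(alpha = 1, beta = 4)
#' mutant_fitness(2, 2, M = 100, params = p)  # (100/2) exp(-1/2) exp(-1)
#' @export
mutant_fitness <- function(m1, m2, M, params) {
  params <- as_survival_params(params)
  M <- check_budget(M)
  if (any(!is.finite(m1)) || any(m1 <= 0) ||
      any(!is.finite(m2)) || any(m2 <= 0)) {
    stop("gamete volumes must be positive", call. = FALSE)
  }
  (M / m1) * gamete_survival(m1, params) * zygote_survival(m1 + m2, params)
}

#' Facultative (viability-effective) gamete volume
#'
#' Motility is assumed to consume a fraction `p` of a gamete's volume, so
#' the volume that contributes to its own viability and to zygote viability
#' is `m * (1 - p)` for a motile gamete and the full `m` for a nonmotile
#' one.
#'
#' @param m Gamete volume(s), um^3, > 0.
#' @param p Motility cost fraction in `[0, 1)`.
#' @param motile Logical; is the gamete motile? Vectorized with `m`.
#' @return Effective volume(s), um^3.
#' @examples
#' facultative_size(100, 0.1, motile = TRUE)   # 90
#' facultative_size(100, 0.1, motile = FALSE)  # 100
#' @export
facultative_size <- function(m, p, motile) {
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("gamete volume m must be positive", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1) {
    stop("motility cost p must lie in [0, 1)", call. = FALSE)
  }
  ifelse(motile, m * (1 - p), m)
}
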