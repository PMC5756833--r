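#' Optimal isogamete volume
#'
#' The evolutionarily stable isogamete volume, i.e. the stationary point of
#' mutant fitness against an identical resident: `alpha + beta/4` for the
#' levitan variant and `beta/4` for the threshold variant. If the threshold
#' optimum falls below the viability threshold `delta` the returned value is
#' `delta`, with attribute `at_viability_threshold = TRUE`.
#'
#' @param params A [survival_params()] object.
#' @return Optimal isogamete volume (um^3).
#' @examples
#' optimal_isogamete_size(survival_params(alpha = 4, beta = 8))  # 6
#' @export
optimal_isogamete_size <- function(params) {
  params <- as_survival_params(params)
  if (params$variant == "levitan") {
    params$alpha + params$beta / 4
  } else {
    m <- params$beta / 4
    if (m < params$delta) {
      structure(params$delta, at_viability_threshold = TRUE)
    } else {
      m
    }
  }
}

#' Is isogamy continuously evolutionarily stable?
#'
#' Isogamy at the optimal isogamete size is continuously evolutionarily
#' stable when `beta < 4 * alpha` (levitan) or `beta < 4 * delta`
#' (threshold). The boundary case is reported as unstable with margin
#' exactly one.
#'
#' @param params A [survival_params()] object.
#' @return A list with elements `stable` (logical) and `margin`
#'   (`beta/(4 alpha)` resp. `beta/(4 delta)`; isogamy is stable iff
#'   margin < 1).
#' @export
isogamy_stable <- function(params) {
  params <- as_survival_params(params)
  scale <- if (params$variant == "levitan") params$alpha else params$delta
  if (params$variant == "threshold" && params$delta == 0) {
    stop("isogamy stability is undefined for threshold variant with delta = 0",
         call. = FALSE)
  }
  margin <- params$beta / (4 * scale)
  list(stable = margin < 1, margin = margin)
}

#' Anisogamous ESS gamete sizes
#'
#' Solves for the dimorphic evolutionarily stable pair of gamete volumes in
#' the unstable-isogamy regime. For the levitan variant the stationarity
#' conditions at a common zygote volume S force S = beta, and the two sizes
#' are the roots of `m^2 - beta m + alpha beta = 0`. For the threshold
#' variant the microgamete sits at the viability threshold (`a = delta`) and
#' the macrogamete solves the zygote-size stationarity condition
#' `(delta + b)^2 = beta b` (larger root, found by bisection).
#'
#' @param params A [survival_params()] object with unstable isogamy
#'   (`isogamy_stable(params)$stable` is `FALSE`).
#' @param M Gamete budget (um^3, > 0); does not affect the ESS sizes but is
#'   carried along for invasion checks.
#' @return An object of class `"ess_result"`: a list with `regime`
#'   (`"anisogamy"`), microgamete volume `a`, macrogamete volume `b`, zygote
#'   volume `S = a + b`, `ratio = b/a`, and `epsilon` (`a - alpha` for
#'   levitan, `a - delta` for threshold).
#' @examples
#' solve_anisogamous_ess(survival_params(alpha = 1, beta = 16), M = 100)
#' @export
solve_anisogamous_ess <- function(params, M = 1) {
  params <- as_survival_params(params)
  M <- check_budget(M)
  st <- isogamy_stable(params)
  if (st$stable) {
    stop("isogamy is stable for these parameters; no anisogamous ESS exists",
         call. = FALSE)
  }
  if (params$variant == "levitan") {
    alpha <- params$alpha
    beta <- params$beta
    disc <- beta^2 - 4 * alpha * beta
    if (disc < 0) {
      stop("stationarity quadratic has no real roots", call. = FALSE)
    }
    a <- (beta - sqrt(disc)) / 2
    b <- (beta + sqrt(disc)) / 2
    eps <- a - alpha
  } else {
    delta <- params$delta
    beta <- params$beta
    a <- delta
    # larger root of (delta + b)^2 = beta b; bracketed by [beta/2, beta]
    h <- function(b) beta * b - (delta + b)^2
    b <- stats::uniroot(h, lower = beta / 2, upper = beta,
                        tol = 1e-10 * beta)$root
    eps <- 0
  }
  structure(
    list(regime = "anisogamy", a = a, b = b, S = a + b, ratio = b / a,
         epsilon = eps, M = M, params = params),
    class = "ess_result"
  )
}

#' @export
print.ess_result <- function(x, ...) {
  cat("Anisogamous ESS (", x$params$variant, " variant)\n", sep = "")
  cat(sprintf("  a = %.6g  b = %.6g  S = %.6g  b/a = %.6g  epsilon = %.3g\n",
              x$a, x$b, x$S, x$ratio, x$epsilon))
  invisible(x)
}

#' Large-beta approximation of the anisogamy ratio
#'
#' In the unstable-isogamy regime with beta large relative to alpha, the
#' microgamete approaches `alpha` (levitan) or `delta` (threshold) and the
#' zygote approaches `beta`, so the ESS anisogamy ratio approaches
#' `(beta - alpha)/alpha` resp. `(beta - delta)/delta`. At the stability
#' boundary (`beta = 4 alpha` resp. `4 delta`) this equals exactly 3, which
#' is the source of the prediction that anisogamous species have gamete
#' volume ratios above three.
#'
#' @param params A [survival_params()] object.
#' @return The approximate anisogamy ratio b/a (dimensionless).
#' @examples
#' predicted_ratio_large_beta(survival_params(alpha = 1, beta = 4))  # 3
#' @export
predicted_ratio_large_beta <- function(params) {
  params <- as_survival_params(params)
  scale <- if (params$variant == "levitan") params$alpha else params$delta
  if (scale <= 0) {
    stop("large-beta ratio requires a positive gamete-survival scale",
         call. = FALSE)
  }
  (params$beta - scale) / scale
}

#' Signed invasion-fitness advantage of a rare mutant
#'
#' Brute-force verification standard for ESS claims. A mutant producing
#' gametes of volume `mutant_m` arises in one mating type, replacing that
#' type's resident, and its gametes fuse with the opposite type's resident
#' gametes. The advantage is the mutant's fitness minus the replaced
#' resident's fitness; at an ESS it is non-positive for every mutant size.
#'
#' @param resident_a,resident_b Resident gamete volumes of the two mating
#'   types (um^3, > 0).
#' @param mutant_m Mutant gamete volume(s) (um^3, > 0). Vectorized.
#' @param M Gamete budget (um^3, > 0).
#' @param params A [survival_params()] object.
#' @param type Which resident the mutant replaces: `"a"` (partners with
#'   `resident_b`) or `"b"` (partners with `resident_a`).
#' @return Signed fitness advantage(s); zero when `mutant_m` equals the
#'   replaced resident.
#' @export
invasion_oracle <- function(resident_a, resident_b, mutant_m, M, params,
                            type = c("a", "b")) {
  type <- match.arg(type)
  params <- as_survival_params(params)
  resident <- if (type == "a") resident_a else resident_b
  partner <- if (type == "a") resident_b else resident_a
  mutant_fitness(mutant_m, partner, M, params) -
    mutant_fitness(resident, partner, M, params)
}

#' Logarithmic size grid for invasion sweeps
#'
#' Gamete sizes span orders of magnitude, so invasion sweeps use a
#' log-spaced grid of `n` candidate mutant sizes on
#' `[beta * 1e-4, beta]`.
#'
#' @param params A [survival_params()] object.
#' @param n Number of grid points.
#' @return Numeric vector of candidate gamete volumes.
#' @export
size_grid <- function(params, n = 1e4) {
  params <- as_survival_params(params)
  exp(seq(log(params$beta * 1e-4), log(params$beta), length.out = n))
}

#' Maximum invasion advantage over a mutant-size grid
#'
#' Sweeps the invasion oracle over a log grid of mutant sizes for both
#' mating types and returns the largest advantage found. A resident pair is
#' numerically uninvadable when this is at most a small tolerance.
#'
#' @inheritParams invasion_oracle
#' @param n Grid size (default 1e4 points).
#' @return Largest signed advantage over the grid and both types.
#' @export
invasion_sweep <- function(resident_a, resident_b, M, params, n = 1e4) {
  grid <- size_grid(params, n)
  max(
    max(invasion_oracle(resident_a, resident_b, grid, M, params, type = "a")),
    max(invasion_oracle(resident_a, resident_b, grid, M, params, type = "b"))
  )
}

# Numeric Hessian of log mutant fitness at the symmetric optimum.
# Returns the two eigenvalues of [[A, B], [B, A]] where A is the own-size
# curvature and B the cross curvature; the symmetric point is a stable
# equilibrium of the two-type adaptive dynamic iff both are negative.
symmetric_stability_eigenvalues <- function(params, M = 1) {
  params <- as_survival_params(params)
  if (params$variant != "levitan") {
    stop("symmetric stability analysis requires the levitan variant",
         call. = FALSE)
  }
  # log of mutant_fitness evaluated in log space (tiny survival
  # probabilities underflow the product form at very small gamete sizes)
  lw <- function(m1, m2) {
    log(M / m1) - params$alpha / m1 - params$beta / (m1 + m2)
  }
  # locate the symmetric optimum numerically: root of the selection gradient
  grad <- function(m) {
    h <- m * 1e-6
    (lw(m + h, m) - lw(m - h, m)) / (2 * h)
  }
  lo <- params$beta * 1e-4
  hi <- params$beta
  m_star <- stats::uniroot(grad, lower = lo, upper = hi,
                           tol = 1e-12 * params$beta)$root
  h <- m_star * 1e-4
  A <- (lw(m_star + h, m_star) - 2 * lw(m_star, m_star) +
          lw(m_star - h, m_star)) / h^2
  B <- (lw(m_star + h, m_star + h) - lw(m_star + h, m_star - h) -
          lw(m_star - h, m_star + h) + lw(m_star - h, m_star - h)) / (4 * h^2)
  c(A + B, A - B)
}

#' Critical beta/alpha ratio for the loss of stable isogamy
#'
#' Locates, by bisection on beta at fixed alpha, the point where the
#' symmetric (isogamous) optimum stops being a stable equilibrium of the
#' two-mating-type adaptive dynamic. Stability is judged from the
#' numerically computed eigenvalues of the Hessian of log mutant fitness at
#' the symmetric optimum, so the result is independent of the closed-form
#' condition `beta < 4 alpha` that it reproduces.
#'
#' @param alpha Gamete-survival scale (um^3, > 0).
#' @param lower,upper Bracket for the critical beta, as multiples of alpha.
#' @param iterations Number of bisection steps.
#' @return The critical ratio beta/alpha (dimensionless).
#' @examples
#' critical_beta_ratio(alpha = 1)
#' @export
critical_beta_ratio <- function(alpha = 1, lower = 2, upper = 8,
                                iterations = 40) {
  stopifnot(alpha > 0, lower > 0, upper > lower)
  unstable <- function(beta) {
    ev <- symmetric_stability_eigenvalues(
      survival_params(alpha = alpha, beta = beta)
    )
    max(ev) > 0
  }
  lo <- lower * alpha
  hi <- upper * alpha
  if (unstable(lo) || !unstable(hi)) {
    stop("bracket does not straddle the stability boundary", call. = FALSE)
  }
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (unstable(mid)) hi <- mid else lo <- mid
  }
  ((lo + hi) / 2) / alpha
}
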