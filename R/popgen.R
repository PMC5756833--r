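#' Configuration of a gamete-size evolution simulation
#'
#' Full parameterization of one run of the haploid two-mating-type
#' recursion. A gamete-size locus, physically linked to the mating-type
#' locus, determines the number `i` of gametogenic mitoses; allele `i`
#' produces gametes of volume `M / 2^i` for `i` in `0..d`. Each generation
#' applies selection within mating types, symmetric stepwise mutation, and
#' multinomial drift applied to each mating type separately (so the "sex
#' ratio" stays one).
#'
#' @param M Gamete budget: reproductive-cell volume (um^3, > 0).
#' @param params A [survival_params()] object.
#' @param d Maximum number of gametogenic mitoses (integer >= 0); the allele
#'   ladder has `d + 1` rungs. Default 9, the maximum observed among the
#'   volvocine algae analysed.
#' @param mu Per-generation mutation probability (each neighbouring rung is
#'   reached with probability `mu/2`). Default `1e-3`.
#' @param N Population size per mating type used for multinomial drift.
#'   `Inf` disables drift (deterministic recursion, for analysis and
#'   testing). Default `1e4`.
#' @param generations Number of generations to iterate. Default `1e4`.
#' @param p Motility cost fraction in `[0, 1)`; 0 disables the motility
#'   locus and runs the pure gamete-size model.
#' @param seed Optional RNG seed recorded with the run.
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(M = 10300, params = survival_params(alpha = 80, beta = 10380))
#' @export
sim_config <- function(M, params, d = 9, mu = 1e-3, N = 1e4,
                       generations = 1e4, p = 0, seed = NULL) {
  M <- check_budget(M)
  params <- as_survival_params(params)
  stopifnot(length(d) == 1L, d >= 0, d == floor(d))
  stopifnot(length(mu) == 1L, mu >= 0, mu < 1)
  stopifnot(length(N) == 1L, N >= 1)
  if (!is.infinite(N)) stopifnot(N == floor(N))
  stopifnot(length(generations) == 1L, generations >= 0,
            generations == floor(generations))
  stopifnot(length(p) == 1L, p >= 0, p < 1)
  structure(
    list(M = M, params = params, d = as.integer(d), mu = mu, N = N,
         generations = as.integer(generations), p = p, seed = seed),
    class = "sim_config"
  )
}

#' Gamete volume produced by a ladder allele
#'
#' Allele `i` corresponds to `i` gametogenic mitoses cutting the budget into
#' `2^i` gametes of volume `M / 2^i`.
#'
#' @param i Allele index (integer in `0..d`). Vectorized.
#' @param M Gamete budget (um^3, > 0).
#' @param d Maximum allele index (for range checking).
#' @return Gamete volume(s), um^3.
#' @examples
#' allele_size(7, M = 10300)  # ~80, the Volvox carteri sperm volume
#' @export
allele_size <- function(i, M, d = 9) {
  M <- check_budget(M)
  if (any(i < 0) || any(i > d) || any(i != floor(i))) {
    stop("allele index must be an integer in 0..d", call. = FALSE)
  }
  M / 2^i
}

#' Create a population state
#'
#' Haplotype frequency vectors for the two mating types. Without the
#' motility locus the haplotype space is the allele ladder `0..d`; with it
#' (`p > 0` in the config) each rung exists in a motile and a nonmotile
#' version.
#'
#' @param freq_plus,freq_minus Nonnegative frequency vectors summing to one,
#'   identically indexed.
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(freq_plus, freq_minus) {
  if (length(freq_plus) != length(freq_minus)) {
    stop("frequency vectors must have identical haplotype indexing",
         call. = FALSE)
  }
  for (v in list(freq_plus, freq_minus)) {
    if (any(v < 0) || abs(sum(v) - 1) > 1e-12) {
      stop("frequencies must be nonnegative and sum to 1 (tol 1e-12)",
           call. = FALSE)
    }
  }
  structure(list(freq_plus = freq_plus, freq_minus = freq_minus),
            class = "population_state")
}

check_state <- function(state) {
  if (!inherits(state, "population_state")) {
    stop("`state` must be a population_state", call. = FALSE)
  }
  for (v in list(state$freq_plus, state$freq_minus)) {
    if (any(v < 0) || abs(sum(v) - 1) > 1e-12) {
      stop("population state is not normalized", call. = FALSE)
    }
  }
  state
}

# Zygote-survival matrix F[i, j] = f(m_i + m_j) over the allele ladder.
zygote_matrix <- function(config) {
  m <- allele_size(0:config$d, config$M, config$d)
  outer(m, m, function(x, y) zygote_survival(x + y, config$params))
}

#' Per-allele fitness within one mating type
#'
#' The fitness of ladder allele `i` in the focal mating type is
#' `(M/m_i) g(m_i) sum_j f(m_i + m_j) x_j`, where the sum runs over the
#' opposite type's allele frequencies `x_j`: an allele's zygotes are as
#' viable as the sizes of the gametes it fuses with.
#'
#' @param state A [population_state()].
#' @param mating_type `"plus"` or `"minus"` (the focal type).
#' @param config A [sim_config()] with `p = 0`.
#' @return Numeric vector of fitnesses, one per ladder allele.
#' @export
fitness_vector <- function(state, mating_type = c("plus", "minus"), config) {
  mating_type <- match.arg(mating_type)
  check_state(state)
  m <- allele_size(0:config$d, config$M, config$d)
  x_opp <- if (mating_type == "plus") state$freq_minus else state$freq_plus
  if (length(x_opp) != length(m)) {
    stop("state indexing does not match the allele ladder", call. = FALSE)
  }
  fert_g <- (config$M / m) * gamete_survival(m, config$params)
  fert_g * as.vector(zygote_matrix(config) %*% x_opp)
}

#' Selection step of the recursion
#'
#' Within each mating type, allele frequencies are reweighted by relative
#' fitness: `y_i = x_i w_i / wbar`, where `wbar` is that type's mean
#' fitness. Selection acts within types because gametes of a type compete
#' with one another for fusions with the opposite type.
#'
#' @inheritParams fitness_vector
#' @return The post-selection [population_state()].
#' @export
selection_step <- function(state, config) {
  check_state(state)
  wp <- fitness_vector(state, "plus", config)
  wm <- fitness_vector(state, "minus", config)
  apply_selection(state, wp, wm)
}

apply_selection <- function(state, wp, wm) {
  sp <- sum(state$freq_plus * wp)
  sm <- sum(state$freq_minus * wm)
  if (!is.finite(sp) || !is.finite(sm) || sp <= 0 || sm <= 0) {
    stop("extinction: mean fitness of a mating type is zero", call. = FALSE)
  }
  population_state(state$freq_plus * wp / sp, state$freq_minus * wm / sm)
}

#' Stepwise mutation matrix for the allele ladder
#'
#' Mutation is symmetric and stepwise: an interior allele mutates to each
#' neighbouring rung with probability `mu/2` per generation (total loss
#' `mu`); the edge alleles 0 and `d` have a single neighbour and lose only
#' `mu/2`. Columns sum to one, so frequency mass is conserved.
#'
#' @param d Maximum allele index.
#' @param mu Per-generation mutation probability.
#' @return A `(d+1) x (d+1)` column-stochastic matrix `T` such that the
#'   post-mutation frequency vector is `T %*% x`.
#' @export
mutation_matrix <- function(d, mu) {
  n <- d + 1L
  T <- diag(n)
  if (n > 1L && mu > 0) {
    for (i in seq_len(n)) {
      nbrs <- c(i - 1L, i + 1L)
      nbrs <- nbrs[nbrs >= 1L & nbrs <= n]
      T[i, i] <- 1 - mu / 2 * length(nbrs)
      for (j in nbrs) T[j, i] <- mu / 2
    }
  }
  T
}

#' Mutation step of the recursion
#'
#' Applies the stepwise [mutation_matrix()] to both mating types.
#'
#' @inheritParams fitness_vector
#' @return The post-mutation [population_state()].
#' @export
mutation_step <- function(state, config) {
  check_state(state)
  T <- mutation_matrix(config$d, config$mu)
  population_state(as.vector(T %*% state$freq_plus),
                   as.vector(T %*% state$freq_minus))
}

#' Genetic-drift step of the recursion
#'
#' Each mating type's frequency vector is replaced by multinomially sampled
#' allele counts divided by `N`, with `N` trials and success probabilities
#' equal to the current frequencies. The two types are sampled
#' independently, maintaining a "sex ratio" of one. Drift is what lets one
#' mating type become statistically linked to one gamete size, so it is
#' required for the evolution of disassortative fusion of dimorphic
#' gametes. With `N = Inf` the state is returned unchanged.
#'
#' @inheritParams fitness_vector
#' @return The post-drift [population_state()].
#' @export
drift_step <- function(state, config) {
  check_state(state)
  if (is.infinite(config$N)) {
    return(state)
  }
  N <- config$N
  population_state(
    as.vector(stats::rmultinom(1, N, state$freq_plus)) / N,
    as.vector(stats::rmultinom(1, N, state$freq_minus)) / N
  )
}

#' Run the gamete-size evolution recursion
#'
#' Iterates selection, then mutation, then drift for
#' `config$generations` generations. Both mating types are initialized
#' fixed on allele 0 (macrogamete isogamy: gametes produced by direct
#' transformation of a reproductive cell) unless `init` overrides this.
#' Modal alleles are read from frequencies time-averaged over the final 10%
#' of generations, which suppresses drift noise in the reported gamete
#' sizes; ties break toward the smaller allele index.
#'
#' @param config A [sim_config()] with `p = 0`.
#' @param init Optional initial [population_state()].
#' @param trajectory If `TRUE`, record the mean gamete volume of each type
#'   every generation.
#' @return An object of class `"sim_outcome"`: a list with
#'   `modal_allele_plus/minus`, `gamete_size_plus/minus` (um^3),
#'   `ratio` (larger modal size over smaller), `classification`
#'   (`"isogamy"` or `"anisogamy"`), time-averaged frequency vectors,
#'   `seed_used`, and optionally a `trajectory` matrix.
#' @examples
#' cfg <- sim_config(M = 100, params = survival_params(alpha = 1, beta = 40),
#'                   d = 4, N = 1000, generations = 200, seed = 1)
#' run_simulation(cfg)
#' @export
run_simulation <- function(config, init = NULL, trajectory = FALSE) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config", call. = FALSE)
  }
  if (config$p > 0) {
    return(run_motility_simulation(config, trajectory = trajectory))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$d + 1L
  m <- allele_size(0:config$d, config$M, config$d)
  if (is.null(init)) {
    f0 <- c(1, rep(0, n - 1L))
    state <- population_state(f0, f0)
  } else {
    state <- check_state(init)
  }

  fert_g <- (config$M / m) * gamete_survival(m, config$params)
  Fz <- zygote_matrix(config)
  Tm <- mutation_matrix(config$d, config$mu)
  gens <- config$generations
  window_start <- gens - max(1L, ceiling(0.1 * gens)) + 1L
  acc_plus <- numeric(n)
  acc_minus <- numeric(n)
  acc_n <- 0L
  traj <- if (trajectory) matrix(NA_real_, nrow = gens, ncol = 2L,
                                 dimnames = list(NULL, c("plus", "minus")))

  for (g in seq_len(gens)) {
    wp <- fert_g * as.vector(Fz %*% state$freq_minus)
    wm <- fert_g * as.vector(Fz %*% state$freq_plus)
    state <- apply_selection(state, wp, wm)
    state <- population_state(as.vector(Tm %*% state$freq_plus),
                              as.vector(Tm %*% state$freq_minus))
    state <- drift_step(state, config)
    if (g >= window_start) {
      acc_plus <- acc_plus + state$freq_plus
      acc_minus <- acc_minus + state$freq_minus
      acc_n <- acc_n + 1L
    }
    if (trajectory) {
      traj[g, ] <- c(sum(m * state$freq_plus), sum(m * state$freq_minus))
    }
  }

  if (acc_n == 0L) {  # generations = 0: report the initial state
    acc_plus <- state$freq_plus
    acc_minus <- state$freq_minus
    acc_n <- 1L
  }
  avg_plus <- acc_plus / acc_n
  avg_minus <- acc_minus / acc_n
  modal_plus <- which.max(avg_plus) - 1L
  modal_minus <- which.max(avg_minus) - 1L
  size_plus <- allele_size(modal_plus, config$M, config$d)
  size_minus <- allele_size(modal_minus, config$M, config$d)
  out <- list(
    modal_allele_plus = modal_plus,
    modal_allele_minus = modal_minus,
    gamete_size_plus = size_plus,
    gamete_size_minus = size_minus,
    ratio = max(size_plus, size_minus) / min(size_plus, size_minus),
    mean_freq_plus = avg_plus,
    mean_freq_minus = avg_minus,
    final_state = state,
    seed_used = config$seed,
    trajectory = if (trajectory) traj
  )
  out$classification <- classify_outcome(out)
  class(out) <- "sim_outcome"
  out
}

#' Classify a simulation outcome as isogamy or anisogamy
#'
#' Anisogamy iff the modal gamete-size alleles of the two mating types
#' differ; the mating-type labels themselves carry no information, so
#' `{0, 7}` and `{7, 0}` are the same outcome.
#'
#' @param outcome A `sim_outcome` from [run_simulation()].
#' @return `"isogamy"` or `"anisogamy"`.
#' @export
classify_outcome <- function(outcome) {
  if (outcome$modal_allele_plus == outcome$modal_allele_minus) {
    "isogamy"
  } else {
    "anisogamy"
  }
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat("Gamete-size simulation outcome\n")
  cat(sprintf("  modal alleles: {%d, %d}  sizes: {%.4g, %.4g} um^3\n",
              x$modal_allele_plus, x$modal_allele_minus,
              x$gamete_size_plus, x$gamete_size_minus))
  cat(sprintf("  ratio: %.4g  classification: %s\n", x$ratio,
              x$classification))
  invisible(x)
}
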