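#' Haplotype table for the size-by-motility model
#'
#' With the motility locus enabled the haplotype space per mating type is
#' the allele ladder crossed with a motility flag: `2 (d + 1)` states,
#' ordered motile rungs `0..d` first, then nonmotile rungs `0..d`.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `allele`, `motile`, `size` (true
#'   volume) and `facultative` (viability-effective volume).
#' @export
motility_haplotypes <- function(config) {
  d <- config$d
  allele <- rep(0:d, 2L)
  motile <- rep(c(TRUE, FALSE), each = d + 1L)
  size <- allele_size(allele, config$M, d)
  data.frame(
    allele = allele, motile = motile, size = size,
    facultative = facultative_size(size, config$p, motile)
  )
}

# Zygote-survival matrix over the motility haplotype space. Entry [i, j] is
# f(fac_i + fac_j) for focal haplotype i fusing with opposite-type haplotype
# j, and 0 for forbidden nonmotile x nonmotile pairings. Excluded partners
# are simply lost fusion opportunities (no renormalization), which is what
# keeps at least one mating type motile.
motility_zygote_matrix <- function(config) {
  hap <- motility_haplotypes(config)
  Fz <- outer(hap$facultative, hap$facultative,
              function(x, y) zygote_survival(x + y, config$params))
  forbidden <- outer(!hap$motile, !hap$motile, `&`)
  Fz[forbidden] <- 0
  Fz
}

#' Per-haplotype fitness with the motility locus
#'
#' The fitness of haplotype `(i, motile?)` in the focal mating type is
#' `(M/m_i) g(fac_i) sum_j f(fac_i + fac_j) x_j`, where `fac` is the
#' facultative volume (`m (1 - p)` if motile, `m` otherwise), and the sum
#' runs over permitted opposite-type partners: motile haplotypes fuse with
#' every partner, nonmotile haplotypes only with motile partners. Fertility
#' `M/m_i` uses the true gamete volume.
#'
#' @param state A [population_state()] over the motility haplotype space.
#' @param mating_type `"plus"` or `"minus"`.
#' @param config A [sim_config()] with `p > 0` (use `p = 0` only to check
#'   the zero-cost limit, where values reduce to [fitness_vector()]).
#' @return Numeric fitness vector over the `2 (d + 1)` haplotypes.
#' @export
motility_fitness_vector <- function(state, mating_type = c("plus", "minus"),
                                    config) {
  mating_type <- match.arg(mating_type)
  check_state(state)
  hap <- motility_haplotypes(config)
  x_opp <- if (mating_type == "plus") state$freq_minus else state$freq_plus
  if (length(x_opp) != nrow(hap)) {
    stop("state indexing does not match the motility haplotype space",
         call. = FALSE)
  }
  fert_g <- (config$M / hap$size) *
    gamete_survival(hap$facultative, config$params)
  fert_g * as.vector(motility_zygote_matrix(config) %*% x_opp)
}

#' Mutation matrix for the size-by-motility haplotype space
#'
#' Two symmetric stepwise channels at rate `mu/2` each: gamete-size steps to
#' neighbouring rungs within a motility class (edge rule as on the plain
#' ladder), and motility flips for each size. An interior motile haplotype
#' therefore keeps mass `1 - 3 mu / 2`.
#'
#' @param d Maximum allele index.
#' @param mu Per-generation mutation probability.
#' @return A `2(d+1) x 2(d+1)` column-stochastic matrix.
#' @export
motility_mutation_matrix <- function(d, mu) {
  Ts <- mutation_matrix(d, mu)
  n <- d + 1L
  flip <- matrix(c(-mu / 2, mu / 2, mu / 2, -mu / 2), 2L, 2L)
  kronecker(diag(2L), Ts) + kronecker(flip, diag(n))
}

#' Mutation step for the motility model
#'
#' @inheritParams motility_fitness_vector
#' @return The post-mutation [population_state()].
#' @export
motility_mutation_step <- function(state, config) {
  check_state(state)
  T <- motility_mutation_matrix(config$d, config$mu)
  population_state(as.vector(T %*% state$freq_plus),
                   as.vector(T %*% state$freq_minus))
}

#' Survival parameters adjusted for microgamete motility
#'
#' Parameters are estimated from observed gamete volumes as in the plain
#' model (`alpha = a`, `beta = a + b`) but account for the reduced
#' facultative volume of the motile microgamete: `alpha = a (1 - p)` and
#' `beta = a (1 - p) + b`, with the macrogamete taken as nonmotile at full
#' facultative volume. This is one admissible reading of the adjustment and
#' is kept as a plain function so alternatives can be swapped in.
#'
#' @param a Microgamete volume (um^3, > 0).
#' @param b Macrogamete volume (um^3, >= a).
#' @param p Motility cost fraction in `[0, 1)`.
#' @return A levitan [survival_params()] object.
#' @examples
#' adjust_params_for_motility(80, 10300, p = 0.5)  # alpha 40, beta 10340
#' @export
adjust_params_for_motility <- function(a, b, p) {
  stopifnot(a > 0, b >= a)
  if (p < 0 || p >= 1) stop("motility cost p must lie in [0, 1)",
                            call. = FALSE)
  survival_params(alpha = a * (1 - p), beta = a * (1 - p) + b)
}

#' Run the gamete-size and motility evolution recursion
#'
#' Same generation loop as [run_simulation()] (selection, mutation, drift)
#' over the size-by-motility haplotype space. Both mating types start fixed
#' on the largest possible motile gamete (allele 0, motile). The
#' macrogamete-producing type is identified as the type with the larger
#' time-averaged mean gamete volume over the final 10% of generations, and
#' the nonmotile fraction reported for it is time-averaged over the same
#' window.
#'
#' @param config A [sim_config()] with `p > 0`.
#' @param trajectory If `TRUE`, record per-generation mean size and
#'   nonmotile fraction for each type.
#' @return An object of class `"motility_outcome"`: modal allele, size and
#'   motility per mating type, `ratio` of modal sizes,
#'   `fraction_nonmotile_macro`, `macro_type`, and a `classification` among
#'   isogamy, anisogamy, pseudooogamy and oogamy.
#' @export
run_motility_simulation <- function(config, trajectory = FALSE) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config", call. = FALSE)
  }
  if (config$p <= 0) {
    stop("the motility model requires a positive motility cost p",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  hap <- motility_haplotypes(config)
  n <- nrow(hap)
  f0 <- numeric(n)
  f0[which(hap$allele == 0L & hap$motile)] <- 1
  state <- population_state(f0, f0)

  fert_g <- (config$M / hap$size) *
    gamete_survival(hap$facultative, config$params)
  Fz <- motility_zygote_matrix(config)
  Tm <- motility_mutation_matrix(config$d, config$mu)
  gens <- config$generations
  window_start <- gens - max(1L, ceiling(0.1 * gens)) + 1L
  acc_plus <- numeric(n)
  acc_minus <- numeric(n)
  acc_n <- 0L
  traj <- if (trajectory) {
    matrix(NA_real_, nrow = gens, ncol = 4L,
           dimnames = list(NULL, c("size_plus", "size_minus",
                                   "nonmotile_plus", "nonmotile_minus")))
  }

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
      traj[g, ] <- c(sum(hap$size * state$freq_plus),
                     sum(hap$size * state$freq_minus),
                     sum(state$freq_plus[!hap$motile]),
                     sum(state$freq_minus[!hap$motile]))
    }
  }
  if (acc_n == 0L) {
    acc_plus <- state$freq_plus
    acc_minus <- state$freq_minus
    acc_n <- 1L
  }
  avg_plus <- acc_plus / acc_n
  avg_minus <- acc_minus / acc_n

  mean_size <- c(plus = sum(hap$size * avg_plus),
                 minus = sum(hap$size * avg_minus))
  macro_type <- names(mean_size)[which.max(mean_size)]
  avg_macro <- if (macro_type == "plus") avg_plus else avg_minus
  frac_nonmotile_macro <- sum(avg_macro[!hap$motile])

  modal_plus <- which.max(avg_plus)
  modal_minus <- which.max(avg_minus)
  size_plus <- hap$size[modal_plus]
  size_minus <- hap$size[modal_minus]
  out <- list(
    modal_allele_plus = hap$allele[modal_plus],
    modal_allele_minus = hap$allele[modal_minus],
    modal_motile_plus = hap$motile[modal_plus],
    modal_motile_minus = hap$motile[modal_minus],
    gamete_size_plus = size_plus,
    gamete_size_minus = size_minus,
    ratio = max(size_plus, size_minus) / min(size_plus, size_minus),
    macro_type = macro_type,
    fraction_nonmotile_macro = frac_nonmotile_macro,
    mean_freq_plus = avg_plus,
    mean_freq_minus = avg_minus,
    haplotypes = hap,
    seed_used = config$seed,
    trajectory = if (trajectory) traj
  )
  out$classification <- classify_motility_outcome(
    size_plus, size_minus, frac_nonmotile_macro
  )
  class(out) <- "motility_outcome"
  out
}

#' Classify a motility-model outcome
#'
#' Mating systems are read off the modal gamete sizes and the nonmotile
#' fraction of the macrogamete-producing type: equal modal sizes across
#' types is isogamy; with dimorphic sizes, a nonmotile macrogamete fraction
#' of at most 5% is anisogamy (both gametes motile), at least 95% is oogamy
#' (egg nonmotile), and anything between is pseudooogamy. The 5%/95% cuts
#' leave wide margins around the ~80% nonmotile fraction characteristic of
#' pseudooogamy.
#'
#' @param size_plus,size_minus Modal gamete volumes of the two types.
#' @param fraction_nonmotile_macro Nonmotile fraction among
#'   macrogamete-type gametes, in `[0, 1]`.
#' @return One of `"isogamy"`, `"anisogamy"`, `"pseudooogamy"`, `"oogamy"`.
#' @export
classify_motility_outcome <- function(size_plus, size_minus,
                                      fraction_nonmotile_macro) {
  stopifnot(fraction_nonmotile_macro >= 0, fraction_nonmotile_macro <= 1)
  if (size_plus == size_minus) {
    "isogamy"
  } else if (fraction_nonmotile_macro <= 0.05) {
    "anisogamy"
  } else if (fraction_nonmotile_macro < 0.95) {
    "pseudooogamy"
  } else {
    "oogamy"
  }
}

#' @export
print.motility_outcome <- function(x, ...) {
  cat("Gamete-size + motility simulation outcome\n")
  cat(sprintf("  modal sizes: {%.4g, %.4g} um^3  ratio: %.4g\n",
              x$gamete_size_plus, x$gamete_size_minus, x$ratio))
  cat(sprintf("  nonmotile macrogamete fraction: %.3f  classification: %s\n",
              x$fraction_nonmotile_macro, x$classification))
  invisible(x)
}
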