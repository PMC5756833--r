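#' Volume of a (prolate) spheroid cell
#'
#' Cells are treated as spheroids or ellipsoids of volume
#' `(4/3) pi r1 r2 r3`. Typically only length and width are reported, in
#' which case callers pass the width radius for both `r2` and `r3` (the
#' third dimension is assumed equal to the width).
#'
#' @param r1,r2,r3 Semi-axes (radii), um, > 0. `r3` defaults to `r2`.
#' @return Volume(s), um^3.
#' @examples
#' spheroid_volume(10, 10, 10)  # sphere, ~4188.79
#' @export
spheroid_volume <- function(r1, r2, r3 = r2) {
  if (any(r1 <= 0) || any(r2 <= 0) || any(r3 <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  (4 / 3) * pi * r1 * r2 * r3
}

# Round log2 exponents half-down: exact .5 ties go to the smaller exponent.
# The small slack absorbs floating-point error in log2 at exact ties.
round_half_down <- function(x) ceiling(x - 0.5 - 1e-9)

#' Snap a measured macro-/isogamete volume to the power-of-two ladder
#'
#' Gametes are the product of 0 or more gametogenic divisions of the
#' reproductive cell, so the ratio `M / b` must be a power of two; measured
#' volumes are adjusted to the nearest rung:
#' `M / 2^round(log2(M / b_measured))`. Exact half-integer ties in the log2
#' exponent round to the smaller exponent (the larger gamete volume),
#' consistent with measuring mature cells at their largest dimensions.
#' Measurement overshoot (`b_measured` slightly above `M`) snaps back to
#' `M`.
#'
#' @param M Reproductive-cell volume (gamete budget), um^3, > 0.
#' @param b_measured Measured gamete volume, um^3, > 0. Vectorized.
#' @return Adjusted gamete volume(s) on the ladder `M / 2^k`, `k >= 0`.
#' @examples
#' snap_power_of_two(11000, 5400)  # 5500
#' snap_power_of_two(950, 900)     # 950
#' @export
snap_power_of_two <- function(M, b_measured) {
  M <- check_budget(M)
  if (any(b_measured <= 0)) {
    stop("measured gamete volume must be positive", call. = FALSE)
  }
  k <- pmax(0, round_half_down(log2(M / b_measured)))
  M / 2^k
}

#' Microgamete volume from the number of gametogenic divisions
#'
#' In species whose macrogamete develops by direct transformation of a
#' reproductive cell while microgametes arise from `n_divisions` sequential
#' mitoses, the microgamete volume is the reproductive-cell volume divided
#' by the number of microgametes, `M / 2^n_divisions`.
#'
#' @param M Reproductive-cell volume, um^3, > 0.
#' @param n_divisions Number of gametogenic mitoses (integer >= 0).
#' @return Microgamete volume, um^3.
#' @examples
#' microgamete_volume(10300, 7)  # ~80 (128 sperm per reproductive cell)
#' @export
microgamete_volume <- function(M, n_divisions) {
  M <- check_budget(M)
  if (any(n_divisions < 0) || any(n_divisions != floor(n_divisions))) {
    stop("n_divisions must be a nonnegative integer", call. = FALSE)
  }
  M / 2^n_divisions
}

species_dimorphism_levels <- c("isogamy", "anisogamy", "anisogamy_internal",
                               "oogamy")
species_grade_levels <- c("unicellular", "colonial", "multicellular")

#' Load a species gamete-size table
#'
#' Reads a tab-separated species table with columns `species`, `n_cells`,
#' `grade`, `dimorphism`, `protoplasmic_volume`, `M` (reproductive-cell
#' volume), `b` (macro-/isogamete volume), `a` (micro-/isogamete volume),
#' `S` (inferred zygote volume) and `ratio` (b/a), volumes in um^3.
#' Dimorphism and grade labels are normalized to lower case
#' (`"anisogamy/internal"` becomes `"anisogamy_internal"`). Row-level
#' checks -- `a <= b <= M`, the printed ratio equalling `b/a` snapped to a
#' power of two, `|a + b - S| <= 2` (printed rounding), and isogamy iff
#' ratio 1 -- are collected as diagnostics in the `"diagnostics"` attribute;
#' violations do not abort the load.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `"species_table"` with a `"diagnostics"`
#'   attribute (character vector, empty when all rows validate).
#' @export
load_species_table <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = TRUE)
  required <- c("species", "n_cells", "grade", "dimorphism",
                "protoplasmic_volume", "M", "b", "a", "S", "ratio")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("species table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl$grade <- tolower(tbl$grade)
  tbl$dimorphism <- gsub("/", "_", tolower(tbl$dimorphism), fixed = TRUE)

  diagnostics <- character(0)
  note <- function(row, msg) {
    sprintf("row %d (%s): %s", row, tbl$species[row], msg)
  }
  for (i in seq_len(nrow(tbl))) {
    if (!tbl$grade[i] %in% species_grade_levels) {
      diagnostics <- c(diagnostics, note(i, paste("unknown grade", tbl$grade[i])))
    }
    if (!tbl$dimorphism[i] %in% species_dimorphism_levels) {
      diagnostics <- c(diagnostics,
                       note(i, paste("unknown dimorphism", tbl$dimorphism[i])))
    }
    if (!(tbl$a[i] <= tbl$b[i] && tbl$b[i] <= tbl$M[i])) {
      diagnostics <- c(diagnostics, note(i, "requires a <= b <= M"))
    }
    snapped_ratio <- 2^round_half_down(log2(tbl$b[i] / tbl$a[i]))
    if (snapped_ratio != tbl$ratio[i]) {
      diagnostics <- c(diagnostics,
                       note(i, sprintf("ratio %s is not b/a snapped to a power of 2 (%s)",
                                       format(tbl$ratio[i]), format(snapped_ratio))))
    }
    if (abs(tbl$a[i] + tbl$b[i] - tbl$S[i]) > 2) {
      diagnostics <- c(diagnostics,
                       note(i, sprintf("a + b = %s differs from printed S = %s by more than 2",
                                       format(tbl$a[i] + tbl$b[i]), format(tbl$S[i]))))
    }
    if ((tbl$dimorphism[i] == "isogamy") != (tbl$ratio[i] == 1)) {
      diagnostics <- c(diagnostics, note(i, "isogamy must coincide with ratio 1"))
    }
  }
  structure(tbl, class = c("species_table", "data.frame"),
            diagnostics = diagnostics)
}

#' The packaged volvocine-algae gamete-size table
#'
#' Loads the packaged table of 45 Chlamydomonadales (volvocine) species
#' with structural grade, gamete dimorphism, protoplasmic volume,
#' reproductive-cell volume, gamete volumes, inferred zygote volume and
#' anisogamy ratio.
#'
#' @return A `"species_table"` data frame (see [load_species_table()]).
#' @examples
#' tbl <- volvocine_table()
#' nrow(tbl)  # 45
#' @export
volvocine_table <- function() {
  load_species_table(
    system.file("extdata", "volvocine_gametes.tsv", package = "anisogamy",
                mustWork = TRUE)
  )
}

as_species_record <- function(record) {
  if (inherits(record, "data.frame")) {
    if (nrow(record) != 1L) {
      stop("`record` must be a single species row", call. = FALSE)
    }
    record <- as.list(record)
  }
  record
}

#' Estimate survival parameters from a species record
#'
#' Under the large-beta approximation the microgamete sits at the
#' gamete-survival scale and the zygote at the zygote-survival scale, so
#' for an anisogamous species `alpha = a` and `beta = S` (falling back to
#' `a + b` when no zygote volume is recorded). The threshold variant puts
#' the viability threshold at the microgamete volume, `delta = a`.
#' Parameters cannot be estimated for isogamous species.
#'
#' @param record A single species row (one-row data frame or list) with
#'   fields `dimorphism`, `a`, `b` and optionally `S`.
#' @param variant `"levitan"` (default) or `"threshold"`.
#' @return A [survival_params()] object.
#' @examples
#' tbl <- volvocine_table()
#' estimate_params(tbl[tbl$species == "Volvox carteri", ])
#' @export
estimate_params <- function(record, variant = c("levitan", "threshold")) {
  variant <- match.arg(variant)
  record <- as_species_record(record)
  if (identical(record$dimorphism, "isogamy")) {
    stop("survival parameters can be estimated only for anisogamous species",
         call. = FALSE)
  }
  beta <- if (!is.null(record$S) && is.finite(record$S)) {
    record$S
  } else {
    record$a + record$b
  }
  if (variant == "levitan") {
    survival_params(alpha = record$a, beta = beta)
  } else {
    survival_params(beta = beta, delta = record$a, variant = "threshold")
  }
}

#' Test the predicted anisogamy-ratio threshold on a species table
#'
#' The disruptive-selection analysis predicts that anisogamous species
#' (including those with internal fertilization and oogamous species) have
#' macro/micro gamete volume ratios above three. This tallies the table
#' against that prediction.
#'
#' @param records A `"species_table"` data frame (or compatible data frame).
#' @return A list with `n_total`, `n_isogamous`, `n_anisogamous`
#'   (dimorphism other than isogamy), `n_anisogamous_ratio_gt_3`, and `pass`
#'   (`TRUE` iff every anisogamous record has ratio > 3).
#' @examples
#' anisogamy_test(volvocine_table())
#' @export
anisogamy_test <- function(records) {
  if (nrow(records) == 0L) stop("empty species table", call. = FALSE)
  aniso <- records$dimorphism != "isogamy"
  list(
    n_total = nrow(records),
    n_isogamous = sum(!aniso),
    n_anisogamous = sum(aniso),
    n_anisogamous_ratio_gt_3 = sum(aniso & records$ratio > 3),
    pass = all(records$ratio[aniso] > 3)
  )
}

#' Fold fitness cost of sex due to anisogamy
#'
#' At equilibrium the fitness of an anisogamous individual is that of the
#' macrogamete producer (zygote numbers are limited by macrogametes),
#' `w_b = (M/b) g(b) f(S)`. A hypothetical isogamous population investing
#' the same total volume has isogamete size `m = (a + b)/2` and fitness
#' `w_m = (M/m) g(m) f(S)`. The fold cost of sex is the ratio:
#' `C = (b/m) g(m)/g(b)` with the levitan gamete-survival function, or
#' `C = b/m = 2 (b/a) / (1 + b/a)` with a survival threshold. The threshold
#' cost approaches the classic twofold cost as the anisogamy ratio grows;
#' the levitan cost is strictly smaller because macrogametes out-survive
#' isogametes.
#'
#' @param a Microgamete volume (um^3, > 0).
#' @param b Macrogamete volume (um^3, >= a).
#' @param params A [survival_params()] object; only `alpha` is used, and
#'   only by the levitan variant.
#' @return Fold cost C (dimensionless, >= 1 for `a <= b`).
#' @examples
#' cost_of_sex(80, 10300, survival_params(alpha = 80, beta = 10380))
#' @export
cost_of_sex <- function(a, b, params) {
  params <- as_survival_params(params)
  if (any(a <= 0)) stop("microgamete volume must be positive", call. = FALSE)
  if (any(a > b)) {
    stop("arguments must satisfy a <= b (micro, then macro)", call. = FALSE)
  }
  m <- (a + b) / 2
  if (params$variant == "levitan") {
    (b / m) * exp(-params$alpha / m) / exp(-params$alpha / b)
  } else {
    b / m
  }
}

#' Inferred zygote volume of a species record
#'
#' The zygote volume is the sum of the fusing gamete volumes, `a + b`. When
#' the record carries a printed zygote volume `S` differing from `a + b` by
#' more than 2 um^3 (beyond printed rounding), a warning is issued.
#'
#' @param record A single species row (one-row data frame or list).
#' @return Zygote volume `a + b`, um^3.
#' @examples
#' tbl <- volvocine_table()
#' zygote_volume(tbl[tbl$species == "Eudorina elegans", ])  # 3682
#' @export
zygote_volume <- function(record) {
  record <- as_species_record(record)
  S <- record$a + record$b
  if (!is.null(record$S) && is.finite(record$S) && abs(S - record$S) > 2) {
    warning(sprintf("a + b = %s differs from recorded zygote volume %s",
                    format(S), format(record$S)), call. = FALSE)
  }
  S
}

#' Per-species quantities behind the summary figures
#'
#' Emits the per-species quantities plotted in the study: inferred zygote
#' volume against protoplasmic volume, anisogamy ratio against protoplasmic
#' volume, and the cost of sex (both survival variants) against the
#' anisogamy ratio for anisogamous species.
#'
#' @param records A `"species_table"` data frame.
#' @return A data frame with one row per species: `species`, `grade`,
#'   `dimorphism`, `protoplasmic_volume`, `zygote_volume`, `ratio`,
#'   `cost_levitan`, `cost_threshold` (costs `NA` for isogamous species).
#' @export
species_figure_quantities <- function(records) {
  aniso <- records$dimorphism != "isogamy"
  cost_lev <- rep(NA_real_, nrow(records))
  cost_thr <- rep(NA_real_, nrow(records))
  for (i in which(aniso)) {
    cost_lev[i] <- cost_of_sex(records$a[i], records$b[i],
                               estimate_params(records[i, ], "levitan"))
    cost_thr[i] <- cost_of_sex(records$a[i], records$b[i],
                               estimate_params(records[i, ], "threshold"))
  }
  data.frame(
    species = records$species,
    grade = records$grade,
    dimorphism = records$dimorphism,
    protoplasmic_volume = records$protoplasmic_volume,
    zygote_volume = records$a + records$b,
    ratio = records$ratio,
    cost_levitan = cost_lev,
    cost_threshold = cost_thr
  )
}
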