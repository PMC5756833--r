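test_that("spheroid volume follows (4/3) pi r1 r2 r3", {
  expect_equal(spheroid_volume(10, 10, 10), 4 / 3 * pi * 1000)
  expect_equal(spheroid_volume(10, 5), 4 / 3 * pi * 250)  # r3 defaults to r2
  expect_equal(spheroid_volume(4, 2, 6), 8 * spheroid_volume(2, 1, 3))
  expect_error(spheroid_volume(0, 1, 1), "positive")
})

test_that("macrogamete volumes snap to the nearest power-of-two rung", {
  expect_equal(snap_power_of_two(11000, 5400), 5500)
  expect_equal(snap_power_of_two(950, 900), 950)
  expect_equal(snap_power_of_two(100, 100), 100)
  # exact half-integer log2 ties round toward the larger gamete
  expect_equal(snap_power_of_two(100, 100 / 2^1.5), 50)
  # measurement overshoot above M snaps back to M
  expect_equal(snap_power_of_two(100, 120), 100)
  expect_error(snap_power_of_two(100, 0), "positive")
})

test_that("microgamete volume divides the budget by the number of gametes", {
  expect_equal(microgamete_volume(10300, 7), 10300 / 128)
  # seven divisions give 128 sperm per reproductive cell
  expect_equal(10300 / microgamete_volume(10300, 7), 128)
  expect_equal(microgamete_volume(5000, 0), 5000)
  expect_error(microgamete_volume(5000, -1), "nonnegative")
})

test_that("the packaged volvocine table loads cleanly and validates", {
  tbl <- volvocine_table()
  expect_s3_class(tbl, "species_table")
  expect_equal(nrow(tbl), 45)
  expect_length(attr(tbl, "diagnostics"), 0)
  expect_true(all(tbl$dimorphism %in%
                    c("isogamy", "anisogamy", "anisogamy_internal", "oogamy")))
  expect_true(all(tbl$grade %in%
                    c("unicellular", "colonial", "multicellular")))
  expect_true(all(tbl$a <= tbl$b & tbl$b <= tbl$M))
  # every printed ratio is b/a snapped to a power of two
  expect_equal(tbl$ratio, 2^round(log2(tbl$b / tbl$a)))
  # printed zygote volumes differ from a + b only by printed rounding
  expect_true(all(abs(tbl$a + tbl$b - tbl$S) <= 2))
})

test_that("the loader reports per-row diagnostics for inconsistent tables", {
  tbl <- volvocine_table()
  bad <- as.data.frame(tbl[1:2, ])
  bad$a[1] <- bad$b[1] * 2          # violates a <= b
  bad$S[2] <- bad$S[2] + 10         # violates the zygote consistency check
  path <- tempfile(fileext = ".tsv")
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  loaded <- load_species_table(path)
  diag <- attr(loaded, "diagnostics")
  expect_gte(length(diag), 2)
  expect_true(any(grepl("a <= b", diag)))
  expect_true(any(grepl("printed S", diag)))
})

test_that("the anisogamy-ratio prediction holds for all 21 anisogamous species", {
  res <- anisogamy_test(volvocine_table())
  expect_equal(res$n_total, 45)
  expect_equal(res$n_anisogamous, 21)
  expect_equal(res$n_isogamous, 24)
  expect_equal(res$n_anisogamous_ratio_gt_3, 21)
  expect_true(res$pass)
  # a dimorphic record at ratio 2 fails the prediction
  toy <- data.frame(dimorphism = c("isogamy", "anisogamy"), ratio = c(1, 2))
  res_toy <- anisogamy_test(toy)
  expect_false(res_toy$pass)
  expect_equal(res_toy$n_anisogamous_ratio_gt_3, 0)
})

test_that("worked rows: zygote volumes and snapped ratios match the table", {
  tbl <- volvocine_table()
  eudorina <- tbl[tbl$species == "Eudorina elegans", ]
  expect_equal(zygote_volume(eudorina), 3682)
  carteria <- tbl[tbl$species == "Carteria palmata", ]
  expect_equal(zygote_volume(carteria), 10160)
  volvox <- tbl[tbl$species == "Volvox carteri", ]
  expect_equal(2^round(log2(volvox$b / volvox$a)), 128)
  expect_equal(volvox$ratio, 128)
  # a discordant printed zygote volume triggers a warning
  off <- as.list(eudorina)
  off$S <- off$S + 10
  expect_warning(zygote_volume(off), "differs")
})

test_that("survival parameters are estimated as alpha = a, beta = S", {
  tbl <- volvocine_table()
  vc <- estimate_params(tbl[tbl$species == "Volvox carteri", ])
  expect_equal(vc$alpha, 80)
  expect_equal(vc$beta, 10380)
  ee <- estimate_params(tbl[tbl$species == "Eudorina elegans", ])
  expect_equal(ee$alpha, 57)
  expect_equal(ee$beta, 3682)
  thr <- estimate_params(tbl[tbl$species == "Volvox carteri", ], "threshold")
  expect_equal(thr$delta, 80)
  expect_equal(thr$beta, 10380)
  # no zygote column: fall back to a + b
  fb <- estimate_params(list(dimorphism = "oogamy", a = 10, b = 90))
  expect_equal(fb$beta, 100)
  expect_error(estimate_params(tbl[tbl$species == "Gonium pectorale", ]),
               "anisogamous")
})

test_that("threshold cost of sex is 2(b/a)/(1 + b/a) and approaches two", {
  thr <- survival_params(beta = 100, delta = 1, variant = "threshold")
  expect_equal(cost_of_sex(5, 5, thr), 1)  # isogamy costs nothing
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, 0.1, 50)
    b <- a * runif(1, 1, 200)
    r <- b / a
    expect_equal(cost_of_sex(a, b, thr), 2 * r / (1 + r))
    expect_equal(cost_of_sex(a, b, thr), b / ((a + b) / 2))
  }
  expect_equal(cost_of_sex(1, 1e8, thr), 2, tolerance = 1e-6)
  expect_error(cost_of_sex(10, 5, thr), "a <= b")
})

test_that("levitan cost of sex is below the threshold cost, ~1.97 for Volvox", {
  tbl <- volvocine_table()
  vc <- tbl[tbl$species == "Volvox carteri", ]
  lev <- cost_of_sex(vc$a, vc$b, estimate_params(vc))
  thr <- cost_of_sex(vc$a, vc$b, estimate_params(vc, "threshold"))
  m <- (vc$a + vc$b) / 2
  expect_equal(lev, (vc$b / m) * exp(-80 / m) / exp(-80 / vc$b))
  expect_equal(thr, 2 * 128.75 / 129.75)
  expect_lt(lev, thr)
  # holds across all anisogamous species with alpha = a
  aniso <- tbl[tbl$dimorphism != "isogamy", ]
  for (i in seq_len(nrow(aniso))) {
    expect_lt(cost_of_sex(aniso$a[i], aniso$b[i], estimate_params(aniso[i, ])),
              cost_of_sex(aniso$a[i], aniso$b[i],
                          estimate_params(aniso[i, ], "threshold")))
  }
})

test_that("estimated parameters round-trip through the ESS solver", {
  # for every anisogamous record, the exact ESS ratio from the estimated
  # parameters is within one ladder step (factor 2) of the printed ratio
  tbl <- volvocine_table()
  aniso <- tbl[tbl$dimorphism != "isogamy", ]
  for (i in seq_len(nrow(aniso))) {
    ess <- solve_anisogamous_ess(estimate_params(aniso[i, ]), M = aniso$M[i])
    expect_gte(ess$ratio, aniso$ratio[i] / 2)
    expect_lte(ess$ratio, aniso$ratio[i] * 2)
  }
})

test_that("figure quantities carry costs for anisogamous species only", {
  tbl <- volvocine_table()
  fq <- species_figure_quantities(tbl)
  expect_equal(nrow(fq), 45)
  iso <- fq$dimorphism == "isogamy"
  expect_true(all(is.na(fq$cost_levitan[iso])))
  expect_true(all(fq$cost_levitan[!iso] > 1))
  expect_true(all(fq$cost_threshold[!iso] < 2))
  expect_equal(fq$zygote_volume, tbl$a + tbl$b)
})
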