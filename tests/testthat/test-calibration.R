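test_that("the physiological filter applies inclusive APD bounds per CL", {
  r <- phys_ranges()
  pass <- fake_record(apd50 = 120, apd90 = 160, cl = 400)
  fail <- fake_record(apd50 = 120, apd90 = 190, cl = 400)
  edge <- fake_record(apd50 = 104, apd90 = 185, cl = 400)   # on the bounds
  recs <- dplyr::bind_rows(pass, fail, edge)
  got <- filter_physiological(recs, r, 400)
  expect_equal(nrow(got), 2L)
  expect_true(all(got$apd90 <= 185))
  # empty table -> empty set
  expect_equal(nrow(filter_physiological(recs[0, ], r, 400)), 0L)
  # unknown CL -> error
  expect_error(filter_physiological(recs, r, 500),
               class = "apopcal_invalid_input")
})

test_that("non-steady and undefined-biomarker records fail calibration", {
  r <- phys_ranges()
  ns <- fake_record(120, 160, steady = FALSE)
  und <- fake_record(NA_real_, 160)
  expect_equal(nrow(filter_physiological(dplyr::bind_rows(ns, und), r, 400)), 0L)
})

test_that("filtering is idempotent and monotone in the ranges", {
  set.seed(3)
  recs <- dplyr::bind_rows(lapply(1:40, function(i)
    fake_record(runif(1, 90, 150), runif(1, 130, 200),
                scales = scale_vector(s_to = 0.5 + i / 40))))
  r <- phys_ranges()
  once <- filter_physiological(recs, r, 400)
  twice <- filter_physiological(once, r, 400)
  expect_equal(as.data.frame(once), as.data.frame(twice))
  # shrinking the ranges never grows the passing set
  shrunk <- r
  shrunk$apd90_hi <- shrunk$apd90_hi - 10
  expect_lte(nrow(filter_physiological(recs, shrunk, 400)), nrow(once))
})

test_that("cross-CL intersections match a brute-force pairwise comparison", {
  set.seed(7)
  mk_set <- function(n) {
    lv <- c(0.7, 0.85, 1, 1.15, 1.3)
    tibble::as_tibble(setNames(
      as.data.frame(matrix(sample(lv, n * 6, replace = TRUE), ncol = 6)),
      scale_cols))
  }
  sets <- list(`400` = mk_set(100), `600` = mk_set(100), `1000` = mk_set(100))
  got <- intersect_across_cls(sets)
  # brute force with string keys
  key <- function(df) unique(do.call(paste, df[scale_cols]))
  k4 <- key(sets$`400`); k6 <- key(sets$`600`); k10 <- key(sets$`1000`)
  expect_equal(nrow(got$cl400_600), length(intersect(k4, k6)))
  expect_equal(nrow(got$cl400_1000), length(intersect(k4, k10)))
  expect_equal(nrow(got$cl600_1000), length(intersect(k6, k10)))
  expect_equal(nrow(got$cl400_600_1000),
               length(intersect(intersect(k4, k6), k10)))
  # intersections are subsets of each single-CL set
  expect_equal(nrow(dplyr::semi_join(got$cl400_600, sets$`400`,
                                     by = scale_cols)),
               nrow(got$cl400_600))
  # identical sets: triple intersection equals each set
  same <- list(`400` = sets$`400`, `600` = sets$`400`, `1000` = sets$`400`)
  expect_equal(nrow(intersect_across_cls(same)$cl400_600_1000),
               length(k4))
  # disjoint sets: all intersections empty
  a <- mk_set(20); a$s_to <- 0.7
  b <- a; b$s_to <- 1.3
  expect_equal(nrow(intersect_across_cls(list(`400` = a, `600` = b))$cl400_600),
               0L)
})

test_that("level distributions count every axis to the set size", {
  g <- default_grid()
  hand <- dplyr::bind_rows(
    scale_vector(s_to = 0.7), scale_vector(s_to = 0.7),
    scale_vector(s_to = 1.3, s_CaL = 1.15))
  d <- level_distribution(hand, g)
  expect_equal(d$n[d$conductance == "to" & d$level == 0.7], 2)
  expect_equal(d$n[d$conductance == "to" & d$level == 1.3], 1)
  expect_equal(d$n[d$conductance == "CaL" & d$level == 1.15], 1)
  sums <- tapply(d$n, d$conductance, sum)
  expect_true(all(sums == 3))
  # empty set -> all zeros
  d0 <- level_distribution(hand[0, ], g)
  expect_true(all(d0$n == 0))
  # full grid passing -> uniform counts |grid| / levels
  dfull <- level_distribution(build_grid(g), g)
  expect_true(all(dfull$n == 15625 / 5))
})

test_that("range extension scales the bounds by the stated fraction", {
  r <- phys_ranges()
  e <- extend_apd_ranges(r, 0.10)
  expect_equal(e$apd90_lo[e$cl == 400], 127.8)
  expect_equal(e$apd90_hi[e$cl == 400], 203.5)
  expect_equal(as.data.frame(extend_apd_ranges(r, 0)), as.data.frame(r))
  # midpoint reading keeps the midpoint fixed
  m <- extend_apd_ranges(r, 0.10, about = "midpoint")
  expect_equal((m$apd90_lo + m$apd90_hi) / 2, (r$apd90_lo + r$apd90_hi) / 2)
  expect_warning(extend_apd_ranges(r, 1), "clamping")
})

test_that("grid expansion follows the trend of passing level indices", {
  g <- default_grid()
  centre <- dplyr::bind_rows(scale_vector(), scale_vector())
  expect_equal(unclass(propose_expanded_grid(centre, g)), unclass(g),
               ignore_attr = TRUE)
  # all passers at the maximum of one axis: offset +2, gain 2 -> +4 steps
  high <- dplyr::bind_rows(scale_vector(s_Ks = 1.3), scale_vector(s_Ks = 1.3))
  e <- propose_expanded_grid(high, g)
  expect_equal(e$Ks, g$Ks + 4 * 0.15)
  expect_equal(e$Kr, g$Kr)
  # symmetric distribution: zero shift
  sym <- dplyr::bind_rows(scale_vector(s_Kr = 0.7), scale_vector(s_Kr = 1.3))
  expect_equal(propose_expanded_grid(sym, g)$Kr, g$Kr)
  expect_error(propose_expanded_grid(centre[0, ], g),
               class = "apopcal_invalid_input")
})

test_that("the published expanded window arises from the default window shifts", {
  # shifting the default axes by the trend steps reproduces the preset
  g <- default_grid()
  shifts <- c(to = 1, Kr = 1, Ks = 5, K1 = 1, CaL = 4, NaK = -1)
  for (ax in conductance_axes())
    expect_equal(g[[ax]] + shifts[[ax]] * 0.15,
                 expanded_mahajan_grid()[[ax]], info = ax)
})

test_that("biomarker histograms bin correctly and conserve counts", {
  recs <- dplyr::bind_rows(lapply(c(101, 104.9, 105, 119, 150, 150, 152,
                                    160, 170, 199), function(a)
    fake_record(a, a + 40)))
  h <- biomarker_histogram(recs, "apd50", 5)
  expect_equal(sum(h$n), 10)
  expect_equal(h$n[h$bin_lo == 100], 2)    # 101 and 104.9
  expect_equal(h$n[h$bin_lo == 105], 1)
  expect_equal(h$n[h$bin_lo == 150], 3)    # 150, 150, 152
  h1 <- biomarker_histogram(recs[1, ], "apd50", 5)
  expect_equal(sum(h1$n), 1)
  expect_error(biomarker_histogram(recs, "nope", 5),
               class = "apopcal_invalid_input")
})

test_that("calibrate summarises counts, intersections and distributions", {
  g <- grid_spec(to = c(0.7, 1.0, 1.3), Kr = c(0.7, 1.0, 1.3),
                 Ks = 1, K1 = 1, CaL = 1, NaK = 1)
  sw <- run_sweep(toy_cell_model(), g, cls = c(400, 600))
  cal <- calibrate(sw, phys_ranges())
  td <- generics::tidy(cal)
  expect_setequal(td$set, c("cl400", "cl600", "cl400_600"))
  expect_true(all(td$n <= 9))
  expect_lte(nrow(cal$intersections$cl400_600),
             min(nrow(cal$per_cl$`400`), nrow(cal$per_cl$`600`)))
  gl <- generics::glance(cal)
  expect_equal(gl$n_population, 9L)
  expect_equal(gl$n_cls, 2L)
  expect_equal(sum(cal$levels$`400`$n[cal$levels$`400`$conductance == "to"]),
               nrow(cal$per_cl$`400`))
})
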