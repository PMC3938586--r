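test_that("NRMSD closed forms", {
  ref <- c(0, 2, 0, 2)
  expect_equal(nrmsd(ref, ref), 0)
  expect_equal(nrmsd(ref + 2, ref), 1)          # offset by the range
  expect_equal(nrmsd(c(1, 1, 1, 1), ref), 0.5)  # RMS 1 / range 2
  expect_error(nrmsd(c(1, 2), c(5, 5)), class = "apopcal_invalid_input")
  expect_error(nrmsd(1:3, 1:4), class = "apopcal_invalid_input")
})

test_that("NRMSD is invariant under common shifts and rescalings", {
  set.seed(21)
  for (i in 1:20) {
    ref <- cumsum(rnorm(50))
    cand <- ref + rnorm(50, sd = 0.3)
    base <- nrmsd(cand, ref)
    shift <- runif(1, -10, 10)
    scale <- runif(1, 0.1, 5)
    expect_equal(nrmsd(cand + shift, ref + shift), base)
    expect_equal(nrmsd(cand * scale, ref * scale), base)
  }
})

test_that("voltage and calcium NRMSD are commensurate on beats", {
  ref <- beat_trace(scale_vector(), 400)
  same <- beat_nrmsd(ref, ref)
  expect_equal(same$v_nrmsd, 0)
  expect_equal(same$ca_nrmsd, 0)
  other <- beat_nrmsd(beat_trace(scale_vector(s_CaL = 1.3), 400), ref)
  expect_gt(other$v_nrmsd, 0)
  expect_equal(other$combined, other$v_nrmsd + other$ca_nrmsd)
})

test_that("NRMSD selection ranks ascending with deterministic tie-breaks", {
  # 10-member hand-scored population
  set.seed(5)
  tbl <- build_grid(grid_spec(to = c(0.7, 0.85, 1, 1.15, 1.3),
                              Kr = c(0.9, 1.1), Ks = 1, K1 = 1,
                              CaL = 1, NaK = 1))
  tbl$v_nrmsd <- c(0.5, 0.1, 0.3, 0.2, 0.05, 0.4, 0.15, 0.25, 0.35, 0.45)
  tbl$ca_nrmsd <- 0
  tbl$combined <- tbl$v_nrmsd
  sel <- select_by_nrmsd(tbl, target_count = 3)
  hand <- tbl[order(tbl$combined), ][1:3, scale_cols]
  expect_equal(as.data.frame(dplyr::arrange(sel$set,
                                            dplyr::across(dplyr::everything()))),
               as.data.frame(dplyr::arrange(hand,
                                            dplyr::across(dplyr::everything()))))
  expect_equal(sel$threshold, 0.15)
  # population of exactly target_count: all selected
  expect_equal(select_by_nrmsd(tbl, 10)$count, 10L)
  # the reference itself (score 0) is always selected
  tbl$combined[7] <- 0
  expect_true(nrow(dplyr::semi_join(select_by_nrmsd(tbl, 1)$set, tbl[7, ],
                                    by = scale_cols)) == 1)
})

test_that("biomarker selection sweeps theta to the closest count", {
  # constructed fixture: 25 records within 1% of the reference APD90, the
  # rest beyond 10%; a target of 25 is met at theta ~ 1
  g5 <- grid_spec(to = c(0.7, 0.85, 1, 1.15, 1.3),
                  Kr = c(0.7, 0.85, 1, 1.15, 1.3),
                  Ks = c(0.7, 1), K1 = 1, CaL = 1, NaK = 1)
  recs <- build_grid(g5)
  n <- nrow(recs)                          # 50
  recs <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    fake_record(120, 160, scales = recs[i, ])))
  ref <- fake_record(120, 160)
  recs$apd90 <- 160 * c(1 + seq(-0.009, 0.009, length.out = 25),
                        1 + seq(0.11, 0.25, length.out = 25))
  sel <- select_by_biomarkers(recs, ref, "apd90", target_count = 25)
  expect_equal(sel$count, 25L)
  expect_lte(sel$threshold, 1)
  expect_gte(sel$threshold, 0.9)
  # population smaller than the target: everything selected at the first
  # theta reaching the full count
  sel_all <- select_by_biomarkers(recs, ref, "apd90", target_count = 100)
  expect_equal(sel_all$count, 50L)
  # undefined biomarkers never match
  recs2 <- recs
  recs2$apd90[1] <- NA
  expect_equal(select_by_biomarkers(recs2, ref, "apd90",
                                    target_count = 100)$count, 49L)
})

test_that("match counts are non-decreasing in theta", {
  set.seed(13)
  g <- build_grid(grid_spec(to = c(0.7, 0.85, 1, 1.15, 1.3),
                            Kr = c(0.7, 0.85, 1, 1.15, 1.3),
                            Ks = 1, K1 = 1, CaL = 1, NaK = 1))
  recs <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i)
    fake_record(120 * runif(1, 0.8, 1.2), 160 * runif(1, 0.8, 1.2),
                scales = g[i, ])))
  ref <- fake_record(120, 160)
  counts <- vapply(seq(0, 30, by = 2), function(th)
    select_by_biomarkers(recs, ref, c("apd50", "apd90"),
                         target_count = 10^9, theta_max = th)$count,
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a zero reference biomarker is rejected by name", {
  ref <- fake_record(120, 160)
  ref$cat_amp <- 0
  expect_error(select_by_biomarkers(fake_record(120, 160), ref, "cat_amp"),
               "cat_amp")
  expect_error(select_by_biomarkers(fake_record(120, 160), ref, "bogus"),
               class = "apopcal_invalid_input")
})

test_that("percentage overlap identities", {
  a <- dplyr::bind_rows(lapply(c(0.7, 0.85, 1), function(x)
    scale_vector(s_to = x)))
  b <- dplyr::bind_rows(lapply(c(0.85, 1, 1.15), function(x)
    scale_vector(s_to = x)))
  expect_equal(percent_overlap(a, a), 100)
  disj <- dplyr::bind_rows(lapply(c(1.15, 1.3), function(x)
    scale_vector(s_Kr = x)))
  expect_equal(percent_overlap(a, disj), 0)
  expect_equal(percent_overlap(a, b), 100 * 2 / 3)
  expect_equal(percent_overlap(a, b, denominator = "union"), 50)
  # |A  B| = 125, |B| = 250 -> 50%
  big_b <- dplyr::bind_rows(lapply(seq_len(250), function(i)
    scale_vector(s_to = 1 + i / 1000)))
  big_a <- big_b[1:125, ]
  expect_equal(percent_overlap(big_a, big_b), 50)
})

test_that("a biomarker that determines NRMSD rank reproduces its selection", {
  # fixture: combined NRMSD is a strictly monotone function of the APD90
  # deviation, so selecting by that single biomarker recovers the NRMSD
  # selection exactly (100% overlap)
  g <- build_grid(grid_spec(to = c(0.7, 0.85, 1, 1.15, 1.3),
                            Kr = c(0.7, 0.85, 1, 1.15, 1.3),
                            Ks = c(0.7, 1.3), K1 = 1, CaL = 1, NaK = 1))
  n <- nrow(g)
  dev <- seq(0.01, 0.6, length.out = n)   # distinct deviations, no ties
  recs <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    fake_record(120, 160 * (1 + dev[i]), scales = g[i, ])))
  ref <- fake_record(120, 160)
  nt <- g
  nt$v_nrmsd <- abs(dev)
  nt$ca_nrmsd <- abs(dev)
  nt$combined <- 2 * abs(dev)
  sel_n <- select_by_nrmsd(nt, target_count = 11)
  sel_b <- select_by_biomarkers(recs, ref, "apd90", target_count = 11)
  expect_equal(percent_overlap(sel_b, sel_n), 100)
  rk <- rank_combinations(recs, sel_n, ref,
                          combinations = list(apd90 = "apd90"),
                          target_count = 11)
  expect_equal(rk$overlap_pct, 100)
  # forcing disjoint selections scores 0
  far <- recs
  far$apd90 <- 1000
  sel_far <- select_by_biomarkers(far[1:5, ], ref, "apd90", target_count = 5)
  expect_equal(percent_overlap(sel_far, sel_n), 0)
})
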