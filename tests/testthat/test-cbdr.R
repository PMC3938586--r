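o_default <- stack_order("to", "Kr", "Ks", "K1", "CaL", "NaK")

test_that("stack orders must be permutations of the six conductances", {
  expect_error(stack_order("to", "to", "Ks", "K1", "CaL", "NaK"),
               class = "apopcal_invalid_input")
  expect_error(stack_order("to", "Kr", "Ks", "K1", "CaL", "Na"),
               class = "apopcal_invalid_input")
})

test_that("stacking maps the 6-D grid bijectively onto the image", {
  g <- grid_L(5)
  vals <- build_grid(g)
  vals$value <- seq_len(nrow(vals))
  img <- stack_image(vals, g, o_default)
  expect_equal(dim(img$img), c(125, 125))
  expect_equal(sum(!is.na(img$img)), 15625)
  expect_setequal(as.vector(img$img), vals$value)   # bijection: all present
  # the all-minimum grid point sits at the bottom-left pixel
  vmin <- vals[vals$s_to == 0.7 & vals$s_Kr == 0.7 & vals$s_Ks == 0.7 &
                 vals$s_K1 == 0.7 & vals$s_CaL == 0.7 & vals$s_NaK == 0.7, ]
  expect_equal(img$img[1, 1], vmin$value)
  # pixel -> grid round trip at random pixels
  set.seed(9)
  lv <- g$to
  for (i in 1:20) {
    row <- sample(0:124, 1); col <- sample(0:124, 1)
    idx <- unstack_pixel(img, row, col)
    pt <- vals
    for (ax in conductance_axes())
      pt <- pt[pt[[paste0("s_", ax)]] == lv[idx[[ax]] + 1], ]
    expect_equal(img$img[row + 1, col + 1], pt$value)
  }
})

test_that("column index arithmetic follows high*L^2 + mid*L + low", {
  g <- grid_L(2)
  vals <- build_grid(g)
  vals$value <- 0
  # order: x slots (low, mid, high) = (to, Kr, Ks); y = (K1, CaL, NaK)
  o <- stack_order("to", "K1", "Kr", "CaL", "Ks", "NaK")
  # point with x indices (low, mid, high) = (1, 0, 1) -> column 1*4+0*2+1 = 5
  pick <- vals$s_to == 1.3 & vals$s_Kr == 0.7 & vals$s_Ks == 1.3 &
    vals$s_K1 == 0.7 & vals$s_CaL == 0.7 & vals$s_NaK == 0.7
  vals$value[pick] <- 99
  img <- stack_image(vals, g, o)
  expect_equal(img$img[0 + 1, 5 + 1], 99)
})

test_that("missing grid points are masked and excluded from the cost", {
  g <- grid_L(2)
  vals <- build_grid(g)
  vals$value <- 1
  img_full <- stack_image(vals, g, o_default)
  expect_equal(clutter_cost(img_full), 0)            # constant image
  img_holes <- stack_image(vals[1:10, ], g, o_default)
  expect_equal(sum(is.na(img_holes$img)), 64 - 10)
  expect_equal(clutter_cost(img_holes), 0)           # masked pairs contribute 0
  img_empty <- stack_image(vals[0, ], g, o_default)
  expect_equal(clutter_cost(img_empty), 0)           # fully masked
})

test_that("clutter cost counts each adjacent pair once", {
  # 2x2 image [[0,1],[2,3]]: |0-1| + |2-3| + |0-2| + |1-3| = 6
  img <- structure(list(img = matrix(c(0, 2, 1, 3), 2, 2), L = NA,
                        order = o_default, value_label = "hand"),
                   class = "stack_image")
  expect_equal(clutter_cost(img), 6)
})

test_that("the optimiser equals an independent brute-force enumeration", {
  set.seed(101)
  g2 <- grid_L(2)
  pts2 <- build_grid(g2)
  for (rep in 1:4) {
    vals <- pts2
    vals$value <- rnorm(nrow(vals))
    fit <- optimize_stack_order(vals, g2)
    expect_equal(fit$cost, oracle_min_cost(vals, g2))
    expect_equal(min(fit$table$cost), fit$cost)
  }
})

test_that("a single influential axis is pushed to a high-order slot", {
  g2 <- grid_L(2)
  vals <- build_grid(g2)
  vals$value <- as.numeric(vals$s_CaL > 1)   # depends on CaL only
  fit <- optimize_stack_order(vals, g2)
  expect_true("CaL" %in% fit$order[c("x_high", "y_high")])
  expect_equal(fit$cost, oracle_min_cost(vals, g2))
})

test_that("constant values cost zero for every order, canonical tie returned", {
  g2 <- grid_L(2)
  vals <- build_grid(g2)
  vals$value <- 7
  fit <- optimize_stack_order(vals, g2)
  expect_equal(fit$cost, 0)
  expect_true(all(fit$table$cost == 0))
  # canonical tie-break: lexicographically smallest slot tuple
  expect_equal(unname(unclass(fit$order)),
               c("CaL", "K1", "Kr", "Ks", "NaK", "to"))
})

test_that("reversing all (x,y) pairs transposes the image at equal cost", {
  set.seed(33)
  g2 <- grid_L(2)
  vals <- build_grid(g2)
  vals$value <- runif(nrow(vals))
  orders <- perms_rec(conductance_axes())[seq(1, 720, by = 37)]
  for (o in orders) {
    fwd <- do.call(stack_order, as.list(o))
    rev <- do.call(stack_order, as.list(o[c(2, 1, 4, 3, 6, 5)]))
    i1 <- stack_image(vals, g2, fwd)
    i2 <- stack_image(vals, g2, rev)
    expect_equal(i2$img, t(i1$img))
    expect_equal(clutter_cost(i1), clutter_cost(i2))
  }
})

test_that("membership stacks encode the CL subsets categorically", {
  g2 <- grid_L(2)
  a <- dplyr::bind_rows(
    build_grid(g2)[1, ],               # passes only at 400
    build_grid(g2)[5, ])               # passes at both
  b <- dplyr::bind_rows(
    build_grid(g2)[5, ],
    build_grid(g2)[9, ])               # passes only at 1000
  ms <- membership_stack(list(`400` = a, `1000` = b), g2, o_default)
  codes <- as.vector(ms$img)
  expect_equal(sum(codes == 1), 1)     # 400 only
  expect_equal(sum(codes == 2), 1)     # 1000 only
  expect_equal(sum(codes == 3), 1)     # both: the intersection category
  expect_equal(sum(codes == 0), 64 - 3)
  expect_equal(ms$categories$label, c("none", "400", "1000", "400+1000"))
  # no passers: every pixel in the "none" category
  ms0 <- membership_stack(list(`400` = a[0, ]), g2, o_default)
  expect_true(all(as.vector(ms0$img) == 0))
})
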