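#' Stack order for dimensional stacking
#'
#' Assigns the six conductances to the six slots of a dimensional stack:
#' the low-order pair spans single pixels, the medium-order pair blocks of
#' L x L pixels, and the high-order pair blocks of L^2 x L^2 pixels. Each
#' conductance must appear exactly once.
#'
#' @param x_low,y_low,x_mid,y_mid,x_high,y_high Conductance names (see
#'   [conductance_axes()]).
#' @return An object of class `stack_order` (named character vector).
#' @export
#' @examples
#' stack_order("to", "Ks", "NaK", "Kr", "CaL", "K1")
stack_order <- function(x_low, y_low, x_mid, y_mid, x_high, y_high) {
  o <- c(x_low = x_low, y_low = y_low, x_mid = x_mid, y_mid = y_mid,
         x_high = x_high, y_high = y_high)
  if (!setequal(o, .axes) || length(unique(o)) != 6L)
    .stop_input("stack order must be a permutation of the six conductances")
  structure(o, class = "stack_order")
}

#' @export
print.stack_order <- function(x, ...) {
  cat("Stack order (x, y), low -> high: ",
      sprintf("(%s, %s) (%s, %s) (%s, %s)\n",
              x[["x_low"]], x[["y_low"]], x[["x_mid"]], x[["y_mid"]],
              x[["x_high"]], x[["y_high"]]))
  invisible(x)
}

# internal: pixel (row, col) 0-based indices for given level-index matrix
# (n x 6, 0-based, columns named by axis) under an order
.stack_rc <- function(idx, order, L) {
  col <- idx[, order[["x_high"]]] * L^2 + idx[, order[["x_mid"]]] * L +
    idx[, order[["x_low"]]]
  row <- idx[, order[["y_high"]]] * L^2 + idx[, order[["y_mid"]]] * L +
    idx[, order[["y_low"]]]
  cbind(row = row, col = col)
}

#' Dimensional stacking of a 6-D grid into a 2-D image
#'
#' Embeds the full factorial grid (L levels per axis) into an L^3 x L^3
#' image. The column index of a grid point is
#' `i(x_high) * L^2 + i(x_mid) * L + i(x_low)` over 0-based level indices,
#' the row index likewise from the y slots; row 0 is at the bottom, so the
#' all-minimum point maps to the bottom-left pixel. Grid points absent from
#' `values` are masked (`NA` pixels).
#'
#' @param values A data frame with the six scale columns plus one value
#'   column (named by `value_col`).
#' @param grid A [grid_spec()] whose axes all have the same level count.
#' @param order A [stack_order()].
#' @param value_col Name of the value column (default: the first
#'   non-scale column).
#' @return An object of class `stack_image`: list with `img` (L^3 x L^3
#'   matrix, `img[1, 1]` = bottom-left), `order`, `L`, `value_label`.
#' @export
#' @examples
#' g <- default_grid()
#' vals <- build_grid(g)
#' vals$value <- steady_apd90(vals, 400)
#' img <- stack_image(vals, g, stack_order("to", "Ks", "NaK", "Kr", "CaL", "K1"))
#' dim(img$img)
stack_image <- function(values, grid, order, value_col = NULL) {
  if (!inherits(grid, "grid_spec")) .stop_input("grid must be a grid_spec")
  if (!inherits(order, "stack_order")) .stop_input("order must be a stack_order")
  Ls <- lengths(grid)
  if (length(unique(Ls)) != 1L)
    .stop_input("all grid axes must have the same number of levels")
  L <- unname(Ls[1L])
  values <- as_tibble(values)
  if (is.null(value_col))
    value_col <- setdiff(names(values), .scale_cols)[1L]
  if (is.na(value_col) || !value_col %in% names(values))
    .stop_input("values must contain a value column")
  validate_scales(values)
  idx <- vapply(.axes, function(ax)
    .level_index(values[[paste0("s_", ax)]], grid[[ax]], ax),
    integer(nrow(values)))
  if (nrow(values) == 1L) idx <- matrix(idx, nrow = 1L,
                                        dimnames = list(NULL, .axes))
  rc <- .stack_rc(idx, order, L)
  img <- matrix(NA_real_, nrow = L^3, ncol = L^3)
  pix <- rc[, "row"] + 1L + rc[, "col"] * L^3
  if (anyDuplicated(pix))
    .stop_input("multiple values map to the same pixel (duplicate grid points)")
  img[pix] <- values[[value_col]]
  structure(list(img = img, order = order, L = L, value_label = value_col),
            class = "stack_image")
}

#' Clutter cost of a stack image
#'
#' The sum over all horizontally and vertically adjacent pixel pairs of the
#' absolute difference of their values, each unordered pair counted once.
#' Pairs involving a masked pixel contribute zero. Minimising this cost
#' over stack orders "smooths" the image, pushing the conductances with
#' the largest effect into the high-order slots.
#'
#' @param img A [stack_image()].
#' @return Non-negative scalar.
#' @export
clutter_cost <- function(img) {
  if (!inherits(img, "stack_image")) .stop_input("img must be a stack_image")
  m <- img$img
  n <- nrow(m)
  sum(abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]), na.rm = TRUE) +
    sum(abs(m[-1L, , drop = FALSE] - m[-n, , drop = FALSE]), na.rm = TRUE)
}

#' Optimal stack order by exhaustive search
#'
#' Evaluates the clutter cost of all 720 assignments of the six
#' conductances to stack slots and returns the minimum. Reversing all
#' three (x, y) pairs transposes the image and leaves the cost unchanged,
#' so minima come in transpose pairs; ties (including those pairs) are
#' broken by the lexicographically smallest slot-name tuple, making the
#' result canonical.
#'
#' @inheritParams stack_image
#' @return An object of class `cbdr_fit`: list with `order` (the optimal
#'   [stack_order()]), `cost`, and `table` (a tibble of all 720 orders and
#'   costs, sorted by cost then order names).
#' @export
#' @examples
#' g <- grid_spec(to = c(0.7, 1.3), Kr = c(0.7, 1.3), Ks = c(0.7, 1.3),
#'                K1 = c(0.7, 1.3), CaL = c(0.7, 1.3), NaK = c(0.7, 1.3))
#' vals <- build_grid(g)
#' vals$value <- steady_apd90(vals, 400)
#' fit <- optimize_stack_order(vals, g)
#' fit$order
optimize_stack_order <- function(values, grid, value_col = NULL) {
  if (!inherits(grid, "grid_spec")) .stop_input("grid must be a grid_spec")
  Ls <- lengths(grid)
  if (length(unique(Ls)) != 1L)
    .stop_input("all grid axes must have the same number of levels")
  L <- unname(Ls[1L])
  values <- as_tibble(values)
  if (is.null(value_col))
    value_col <- setdiff(names(values), .scale_cols)[1L]
  validate_scales(values)
  idx <- vapply(.axes, function(ax)
    .level_index(values[[paste0("s_", ax)]], grid[[ax]], ax),
    integer(nrow(values)))
  v <- values[[value_col]]
  n3 <- L^3

  perms <- pracma::perms(1:6)   # all 720 slot assignments
  slot_names <- c("x_low", "y_low", "x_mid", "y_mid", "x_high", "y_high")
  costs <- numeric(nrow(perms))
  img <- matrix(NA_real_, n3, n3)
  for (p in seq_len(nrow(perms))) {
    o <- setNames(.axes[perms[p, ]], slot_names)
    rc <- .stack_rc(idx, o, L)
    img[] <- NA_real_
    img[rc[, "row"] + 1L + rc[, "col"] * n3] <- v
    costs[p] <- sum(abs(img[, -1L] - img[, -n3]), na.rm = TRUE) +
      sum(abs(img[-1L, ] - img[-n3, ]), na.rm = TRUE)
  }
  name_of <- function(p) paste(.axes[perms[p, ]], collapse = ",")
  nms <- vapply(seq_len(nrow(perms)), name_of, character(1))
  ord <- order(costs, nms)
  best <- ord[1L]
  tab <- tibble(
    x_low = .axes[perms[ord, 1L]], y_low = .axes[perms[ord, 2L]],
    x_mid = .axes[perms[ord, 3L]], y_mid = .axes[perms[ord, 4L]],
    x_high = .axes[perms[ord, 5L]], y_high = .axes[perms[ord, 6L]],
    cost = costs[ord]
  )
  structure(list(
    order = do.call(stack_order, as.list(.axes[perms[best, ]])),
    cost = costs[best],
    table = tab
  ), class = "cbdr_fit")
}

#' @export
print.cbdr_fit <- function(x, ...) {
  cat("# Clutter-based dimension reordering (exhaustive over 720 orders)\n")
  print(x$order)
  cat("Cost:", format(x$cost), "\n")
  invisible(x)
}

#' Categorical membership stack across cycle lengths
#'
#' Encodes, for every grid point, the subset of cycle lengths at which it
#' passed calibration, and stacks the codes into an image. Code 0 means
#' "passed nowhere"; the attached `categories` table maps each code to a
#' label such as `"400+1000"`.
#'
#' @param passing_sets Named list (names = CLs) of data frames of passing
#'   scale vectors.
#' @param grid A [grid_spec()] with equal level counts.
#' @param order A [stack_order()] (the unoptimised default order is
#'   conventional here, so stacks of different biomarkers stay comparable).
#' @return A `stack_image` whose `categories` field maps codes to CL-subset
#'   labels.
#' @export
membership_stack <- function(passing_sets, grid, order) {
  if (!length(passing_sets) || is.null(names(passing_sets)))
    .stop_input("passing_sets must be a named (by CL) list")
  cls <- names(passing_sets)
  pts <- build_grid(grid)
  code <- rep(0L, nrow(pts))
  key <- do.call(paste, pts[.scale_cols])
  for (i in seq_along(cls)) {
    ps <- as_tibble(passing_sets[[i]])
    if (nrow(ps)) {
      pk <- do.call(paste, validate_scales(ps)[.scale_cols])
      code <- code + bitwShiftL(1L, i - 1L) * as.integer(key %in% pk)
    }
  }
  labels <- vapply(0:(2^length(cls) - 1L), function(cd) {
    inc <- cls[bitwAnd(cd, bitwShiftL(1L, seq_along(cls) - 1L)) > 0]
    if (!length(inc)) "none" else paste(inc, collapse = "+")
  }, character(1))
  vals <- pts
  vals$membership <- as.numeric(code)
  img <- stack_image(vals, grid, order, value_col = "membership")
  img$categories <- tibble(code = 0:(2^length(cls) - 1L), label = labels)
  img
}

#' Round-trip a stack image pixel back to its grid point
#'
#' Inverse of the pixel mapping used by [stack_image()]: for 0-based pixel
#' `(row, col)` returns the 0-based level index of every conductance.
#'
#' @param img A `stack_image`.
#' @param row,col 0-based pixel indices.
#' @return Named integer vector over [conductance_axes()].
#' @export
unstack_pixel <- function(img, row, col) {
  L <- img$L
  o <- img$order
  idx <- integer(6)
  names(idx) <- .axes
  idx[o[["x_high"]]] <- col %/% L^2
  idx[o[["x_mid"]]] <- (col %/% L) %% L
  idx[o[["x_low"]]] <- col %% L
  idx[o[["y_high"]]] <- row %/% L^2
  idx[o[["y_mid"]]] <- (row %/% L) %% L
  idx[o[["y_low"]]] <- row %% L
  idx
}

#' Export a stack image as a CSV matrix
#'
#' Writes the image as a plain numeric matrix (rows top-to-bottom, so the
#' file reads like the plot; masked pixels empty).
#'
#' @param img A `stack_image`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack_csv <- function(img, path) {
  m <- img$img[rev(seq_len(nrow(img$img))), , drop = FALSE]
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
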