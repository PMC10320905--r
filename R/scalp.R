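#' Topographic scalp map of a per-channel metric
#'
#' Min-max normalises the channel values against a pooled reference (by
#' default the values themselves; supply the subject's task-pooled values to
#' normalise relative to all tasks) and interpolates them over the head disc
#' with a thin-plate-spline radial basis function through the electrode
#' positions. Grid values are clipped to the normalised range and masked
#' outside the unit head circle.
#'
#' @param values Named numeric vector of per-channel metric values.
#' @param montage Montage tibble with columns `label`, `x`, `y` (see
#'   [montage_1010()]); every channel in `values` must be present.
#' @param pool Values defining the normalisation range (default `values`).
#' @param grid_n Grid resolution per axis (default 64).
#' @param normalise If `FALSE`, skip min-max scaling (values are assumed to be
#'   already normalised) and only clip to `[-1, 1]`.
#' @return An object of class `scalp_map`: `channels` (tibble label, x, y,
#'   value), `grid_x`, `grid_y` (axis vectors) and `grid_z` (matrix, `NA`
#'   outside the head circle).
#' @export
#' @examples
#' m <- montage_1010()
#' v <- stats::setNames(seq_along(motor_channels()), motor_channels())
#' sm <- scalp_map(v, m)
#' range(sm$grid_z, na.rm = TRUE)
scalp_map <- function(values, montage, pool = values, grid_n = 64,
                      normalise = TRUE) {
  if (is.null(names(values))) stop("`values` must be named by channel", call. = FALSE)
  missing <- setdiff(names(values), montage$label)
  if (length(missing)) {
    stop("channel(s) missing from montage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- if (normalise) minmax_normalise(values, pool = pool) else values
  v <- v[order(names(v))]  # canonical order: result independent of input order
  pos <- montage[match(names(v), montage$label), ]
  px <- pos$x; py <- pos$y
  n <- length(v)

  # anchor the head-circle boundary with ghost points carrying the nearest
  # electrode's value, so the spline cannot extrapolate freely beyond the
  # electrode hull
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  bx <- 1.05 * sin(ang); by <- 1.05 * cos(ang)
  nearest <- vapply(seq_along(bx), function(i) {
    which.min((px - bx[i])^2 + (py - by[i])^2)
  }, integer(1))
  ix <- c(px, bx); iy <- c(py, by)
  iv <- c(as.numeric(v), as.numeric(v)[nearest])

  # thin-plate spline phi(r) = r^2 log r with affine polynomial part
  phi <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  m <- length(ix)
  K <- phi(outer(ix, ix, "-")^2 + outer(iy, iy, "-")^2)
  P <- cbind(1, ix, iy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(iv, 0, 0, 0)
  coef <- solve(A, rhs)
  w <- coef[seq_len(m)]
  a <- coef[m + 1:3]

  ax <- seq(-1, 1, length.out = grid_n)
  gx <- rep(ax, times = grid_n)
  gy <- rep(ax, each = grid_n)
  G <- phi(outer(gx, ix, "-")^2 + outer(gy, iy, "-")^2)
  z <- as.numeric(G %*% w) + a[1] + a[2] * gx + a[3] * gy
  lim <- if (normalise) c(-1, 1) else range(c(-1, 1, v))
  z <- pmin(pmax(z, lim[1]), lim[2])
  z[gx^2 + gy^2 > 1] <- NA
  structure(list(
    channels = tibble::tibble(label = names(v), x = px, y = py,
                              value = as.numeric(v)),
    grid_x = ax, grid_y = ax,
    grid_z = matrix(z, grid_n, grid_n)  # rows follow grid_x, cols grid_y
  ), class = "scalp_map")
}

#' @export
print.scalp_map <- function(x, ...) {
  cat(sprintf("<scalp_map> %d electrodes, %dx%d grid, range [%.2f, %.2f]\n",
              nrow(x$channels), length(x$grid_x), length(x$grid_y),
              min(x$grid_z, na.rm = TRUE), max(x$grid_z, na.rm = TRUE)))
  invisible(x)
}

#' Electrode nearest to the interpolated scalp-map maximum
#' @param map A `scalp_map`.
#' @return The label of the electrode closest to the grid maximum.
#' @export
scalp_map_peak <- function(map) {
  stopifnot(inherits(map, "scalp_map"))
  idx <- which(map$grid_z == max(map$grid_z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  gx <- map$grid_x[idx[1]]
  gy <- map$grid_y[idx[2]]
  d2 <- (map$channels$x - gx)^2 + (map$channels$y - gy)^2
  map$channels$label[which.min(d2)]
}

#' Plot a scalp map
#'
#' Renders the interpolated head-disc grid with a blue-white-red palette
#' (red = 1 maximum, blue = -1 minimum) and electrode markers. Uses ggplot2
#' when available.
#'
#' @param x A `scalp_map`.
#' @param ... Unused.
#' @return A ggplot object (invisibly, after printing nothing).
#' @export
plot.scalp_map <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting scalp maps", call. = FALSE)
  }
  df <- expand.grid(x = x$grid_x, y = x$grid_y)
  df$z <- as.numeric(x$grid_z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$z)) +
    ggplot2::geom_raster(na.rm = TRUE) +
    ggplot2::geom_point(data = x$channels, ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, size = 0.6) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), na.value = "transparent") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
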