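#' The 18 motor-area channels
#'
#' Channel labels over the sensorimotor cortex used for periodograms, band
#' powers and paired statistics: the frontocentral, central and centroparietal
#' rows FC1-FC6, C1-C6 and CP1-CP6.
#'
#' @return Character vector of 18 channel labels.
#' @export
#' @examples
#' motor_channels()
motor_channels <- function() {
  c(sprintf("FC%d", 1:6), sprintf("C%d", 1:6), sprintf("CP%d", 1:6))
}

# Row and column geometry of the extended 10-10 grid. Angles in degrees:
# `sag` is the arc from the vertex along the midline (anterior positive),
# `lat` the arc from the midline along the crossing arc (right positive).
.montage_rows <- list(
  Fp = list(sag = 72, cols = c(1, 0, 2)),
  AF = list(sag = 54, cols = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
  F  = list(sag = 36, cols = c(9, 7, 5, 3, 1, 0, 2, 4, 6, 8, 10)),
  FC = list(sag = 18, cols = c(9, 7, 5, 3, 1, 0, 2, 4, 6, 8, 10)),
  C  = list(sag = 0,  cols = c(9, 7, 5, 3, 1, 0, 2, 4, 6, 8, 10)),
  CP = list(sag = -18, cols = c(9, 7, 5, 3, 1, 0, 2, 4, 6, 8, 10)),
  P  = list(sag = -36, cols = c(9, 7, 5, 3, 1, 0, 2, 4, 6, 8, 10)),
  PO = list(sag = -54, cols = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
  O  = list(sag = -72, cols = c(1, 0, 2))
)

# Naming irregularities of the 10-10 system: the 7/8 and 9/10 columns of some
# rows carry the temporal prefixes instead of the row prefix.
.montage_label <- function(row, col) {
  if (col == 0) return(paste0(row, "z"))
  if (row == "FC" && col >= 7) row <- "FT"
  if (row == "C" && col >= 7) row <- "T"
  if (row == "CP" && col >= 7) row <- "TP"
  paste0(row, col)
}

#' Standard 10-10 montage (80 channels)
#'
#' Electrode positions for an 80-channel wet-electrode cap laid out on the
#' extended international 10-10 grid. Positions are computed from the grid's
#' crossing-arc geometry on a unit sphere: 2-D coordinates are the azimuthal
#' equidistant projection from the vertex, scaled so the head circle
#' (nasion-inion-preauricular level) has radius 1; electrodes of the 9/10
#' column and Iz lie 10% below that circle and so project slightly outside it.
#'
#' @return A tibble with columns `label`, `x`, `y` (2-D head-disc projection)
#'   and `x3`, `y3`, `z3` (unit-sphere coordinates).
#' @export
#' @examples
#' m <- montage_1010()
#' nrow(m)                       # 80 electrodes
#' all(motor_channels() %in% m$label)
montage_1010 <- function() {
  rows <- list()
  for (row in names(.montage_rows)) {
    geom <- .montage_rows[[row]]
    for (col in geom$cols) {
      side <- if (col == 0) 0 else if (col %% 2 == 1) -1 else 1
      ring <- if (col == 0) 0 else ceiling(col / 2)
      rows[[length(rows) + 1L]] <- list(
        label = .montage_label(row, col),
        sag = geom$sag, lat = side * 18 * ring
      )
    }
  }
  rows[[length(rows) + 1L]] <- list(label = "Iz", sag = -90, lat = 0)

  out <- do.call(rbind, lapply(rows, function(e) {
    sag <- e$sag * pi / 180
    lat <- e$lat * pi / 180
    if (abs(e$lat) >= 90 - 1e-9 || abs(e$sag) >= 90 - 1e-9) {
      # 9/10 column and Iz: 10% below the head circle along the spoke of the
      # corresponding on-circle position (the crossing-arc formula degenerates
      # at 90 degrees).
      inner <- sign(e$lat) * 72 * pi / 180
      if (abs(e$sag) >= 90 - 1e-9) {
        az <- atan2(0, sign(e$sag))
      } else {
        x0 <- sin(inner)
        y0 <- cos(inner) * sin(sag)
        az <- atan2(x0, y0)
      }
      gamma <- 108 * pi / 180
    } else {
      x0 <- sin(lat)
      y0 <- cos(lat) * sin(sag)
      z0 <- cos(lat) * cos(sag)
      gamma <- acos(z0)
      az <- atan2(x0, y0)
    }
    r2 <- gamma / (pi / 2)
    data.frame(
      label = e$label,
      x = r2 * sin(az), y = r2 * cos(az),
      x3 = sin(gamma) * sin(az), y3 = sin(gamma) * cos(az), z3 = cos(gamma),
      stringsAsFactors = FALSE
    )
  }))
  stopifnot(!anyDuplicated(out$label))
  tibble::as_tibble(out)
}
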