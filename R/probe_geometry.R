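# Probe layout construction and geometric queries.
#
# Coordinate convention: x lateral (µm), y depth (µm, positive down,
# 0 = topmost site row). Per-shank local coordinates plus a shank offset of
# shank_index * shank_pitch. Indices are 0-based in serialized files and
# 1-based inside R (documented on each accessor).

#' Build a multi-shank optoelectrode layout
#'
#' Constructs the site and micro-LED geometry of a multi-shank silicon
#' optoelectrode. Defaults describe a 4-shank device with 64 recording sites
#' and 32 LEDs per shank: two staggered columns of 32 sites each (40 µm
#' vertical pitch within a column, 27 µm between columns, 20 µm vertical
#' stagger) and a single central LED column at 40 µm pitch.
#'
#' @param n_shanks number of shanks (default 4).
#' @param shank_pitch_um center-to-center distance between shanks (µm).
#' @param sites_per_column sites per column per shank (two columns; default 32).
#' @param leds_per_shank LEDs per shank (default 32).
#' @param row_pitch_um vertical site pitch within a column (µm, default 40).
#' @param column_offset_um horizontal distance between the two site columns
#'   (µm, default 27).
#' @param stagger_um vertical offset of the second column relative to the
#'   first (µm, default 20, i.e. half the row pitch so rows interleave).
#' @param led_pitch_um vertical LED pitch (µm, default 40).
#' @param site_w_um,site_h_um site width/height (µm).
#' @param led_w_um,led_h_um LED width/height (µm).
#' @param shank_length_um,shank_thickness_um shank dimensions (µm).
#' @return An object of class `probe_layout`: a list with `sites` and `leds`
#'   data frames (`shank`, `column`, `x_um`, `y_um`) plus the scalar
#'   parameters.
#' @examples
#' lay <- build_layout()
#' nrow(lay$sites) # 256
#' nrow(lay$leds)  # 128
#' @export
build_layout <- function(n_shanks = 4L,
                         shank_pitch_um = 300,
                         sites_per_column = 32L,
                         leds_per_shank = 32L,
                         row_pitch_um = 40,
                         column_offset_um = 27,
                         stagger_um = 20,
                         led_pitch_um = 40,
                         site_w_um = 11, site_h_um = 15,
                         led_w_um = 8, led_h_um = 15,
                         shank_length_um = 6000,
                         shank_thickness_um = 30) {
  n_shanks <- as.integer(n_shanks)
  sites_per_column <- as.integer(sites_per_column)
  leds_per_shank <- as.integer(leds_per_shank)
  if (is.na(n_shanks) || n_shanks < 1L)
    stop("n_shanks must be a positive integer")
  if (sites_per_column < 1L || leds_per_shank < 1L)
    stop("site and LED counts must be positive")
  if (shank_pitch_um <= 0 || row_pitch_um <= 0 || led_pitch_um <= 0)
    stop("pitches must be positive")
  if (column_offset_um < 0 || stagger_um < 0)
    stop("column offset and stagger must be non-negative")

  sites <- do.call(rbind, lapply(seq_len(n_shanks) - 1L, function(s) {
    x0 <- s * shank_pitch_um
    col0 <- data.frame(
      shank = s, column = 0L,
      x_um = x0 - column_offset_um / 2,
      y_um = (seq_len(sites_per_column) - 1L) * row_pitch_um
    )
    col1 <- data.frame(
      shank = s, column = 1L,
      x_um = x0 + column_offset_um / 2,
      y_um = (seq_len(sites_per_column) - 1L) * row_pitch_um + stagger_um
    )
    rbind(col0, col1)
  }))
  # interleave by depth within each shank so site index follows depth order
  sites <- sites[order(sites$shank, sites$y_um, sites$column), ]
  rownames(sites) <- NULL

  leds <- do.call(rbind, lapply(seq_len(n_shanks) - 1L, function(s) {
    data.frame(
      shank = s,
      x_um = s * shank_pitch_um,
      y_um = (seq_len(leds_per_shank) - 1L) * led_pitch_um
    )
  }))
  rownames(leds) <- NULL

  structure(list(
    n_shanks = n_shanks,
    shank_pitch_um = shank_pitch_um,
    sites_per_column = sites_per_column,
    leds_per_shank = leds_per_shank,
    row_pitch_um = row_pitch_um,
    column_offset_um = column_offset_um,
    stagger_um = stagger_um,
    led_pitch_um = led_pitch_um,
    site_w_um = site_w_um, site_h_um = site_h_um,
    led_w_um = led_w_um, led_h_um = led_h_um,
    shank_length_um = shank_length_um,
    shank_thickness_um = shank_thickness_um,
    sites = sites,
    leds = leds
  ), class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf(
    "probe_layout: %d shank(s) at %g um pitch, %d sites, %d LEDs\n",
    x$n_shanks, x$shank_pitch_um, nrow(x$sites), nrow(x$leds)
  ))
  cat(sprintf("  span area: %.3f mm^2\n",
              suppressWarnings(span_area(x))))
  invisible(x)
}

#' Center-to-center distances between adjacent recording sites
#'
#' For every site, the distance to its nearest neighbour in the same column
#' (next row) and to the nearest site in the other column of the same shank.
#' On the default layout the maximum is the 40 µm within-column pitch and the
#' staggered cross-column distance is sqrt(27^2 + 20^2) ~= 33.6 µm.
#'
#' @param layout a `probe_layout`.
#' @return data frame with `site_a`, `site_b` (1-based row indices into
#'   `layout$sites`) and `dist_um`; zero rows if no site has a neighbour.
#' @export
adjacent_site_distances <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  s <- layout$sites
  out <- list()
  for (sh in unique(s$shank)) {
    idx <- which(s$shank == sh)
    for (co in c(0L, 1L)) {
      cidx <- idx[s$column[idx] == co]
      if (length(cidx) >= 2L) {
        cidx <- cidx[order(s$y_um[cidx])]
        a <- cidx[-length(cidx)]; b <- cidx[-1L]
        out[[length(out) + 1L]] <- data.frame(
          site_a = a, site_b = b,
          dist_um = sqrt((s$x_um[a] - s$x_um[b])^2 + (s$y_um[a] - s$y_um[b])^2)
        )
      }
      oidx <- idx[s$column[idx] != co]
      if (length(cidx) >= 1L && length(oidx) >= 1L) {
        nn <- vapply(cidx, function(i) {
          d <- sqrt((s$x_um[i] - s$x_um[oidx])^2 + (s$y_um[i] - s$y_um[oidx])^2)
          j <- oidx[which.min(d)]
          c(j, min(d))
        }, numeric(2))
        out[[length(out) + 1L]] <- data.frame(
          site_a = cidx, site_b = as.integer(nn[1L, ]), dist_um = nn[2L, ]
        )
      }
    }
  }
  if (!length(out))
    return(data.frame(site_a = integer(), site_b = integer(),
                      dist_um = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Brain area spanned by the recording sites
#'
#' Horizontal extent of the shank centers times the vertical extent of the
#' active site rows, in mm^2. The vertical extent is measured in full
#' row-pitch sampling slots (each interleaved site row samples one 40-µm
#' slot), i.e. `sites_per_column * row_pitch + stagger`; for the default
#' device this gives 900 µm x 1300 µm = 1.17 mm^2.
#'
#' @param layout a `probe_layout`.
#' @return span in mm^2 (0 with a warning for a single-shank layout).
#' @export
span_area <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  horiz_um <- (layout$n_shanks - 1L) * layout$shank_pitch_um
  vert_um <- layout$sites_per_column * layout$row_pitch_um + layout$stagger_um
  if (horiz_um <= 0) {
    warning("layout has zero horizontal extent; span area is 0")
    return(0)
  }
  (horiz_um / 1000) * (vert_um / 1000)
}

#' Nearest LED to a recording site
#'
#' Euclidean nearest LED on the same shank as the given site. Ties are broken
#' toward the lower LED index.
#'
#' @param layout a `probe_layout`.
#' @param site_index 1-based row index into `layout$sites`.
#' @return list with `led_index` (1-based row index into `layout$leds`) and
#'   `dist_um`.
#' @export
nearest_led <- function(layout, site_index) {
  stopifnot(inherits(layout, "probe_layout"))
  site_index <- as.integer(site_index)
  if (is.na(site_index) || site_index < 1L || site_index > nrow(layout$sites))
    stop("site_index out of range")
  st <- layout$sites[site_index, ]
  cand <- which(layout$leds$shank == st$shank)
  d <- sqrt((layout$leds$x_um[cand] - st$x_um)^2 +
            (layout$leds$y_um[cand] - st$y_um)^2)
  k <- which(d == min(d))[1L] # deterministic tie-break: lower LED index
  list(led_index = cand[k], dist_um = d[k])
}

#' Write / read a probe layout as JSON
#'
#' Serializes coordinates with an explicit units field; indices are 0-based
#' on disk.
#'
#' @param layout a `probe_layout`.
#' @param path file path.
#' @return `read_layout` returns a `probe_layout`; `write_layout` returns
#'   `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "probe_layout"))
  doc <- unclass(layout)
  doc$units <- list(position = "um")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$units <- NULL
  doc$sites <- as.data.frame(doc$sites)
  doc$leds <- as.data.frame(doc$leds)
  for (f in c("n_shanks", "sites_per_column", "leds_per_shank"))
    doc[[f]] <- as.integer(doc[[f]])
  doc$sites$shank <- as.integer(doc$sites$shank)
  doc$sites$column <- as.integer(doc$sites$column)
  doc$leds$shank <- as.integer(doc$leds$shank)
  structure(doc, class = "probe_layout")
}
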