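# The wallpaper lattice generated by the cruciform rule, and polygonal-line
# renderings of sequence vectors (place number on x, phase index on y).

#' Letter at arbitrary lattice coordinates
#'
#' The lattice cell at `(x, y)` (x right, y up, origin `(0, 0)`) holds the
#' base with index `(origin_index + x + 2y) mod 5`; moving right applies `r`,
#' moving up applies `u`.  Negative coordinates are allowed.
#'
#' @param x,y Integer vectors (recycled).
#' @param origin Base letter at the origin (default `"E"`).
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return Character vector of letters.
#' @examples
#' grid_letter(1, 0)  # "C"
#' grid_letter(0, 1)  # "A"
#' @export
grid_letter <- function(x, y, origin = "E", alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  m0 <- base_index(origin, alphabet)
  base_letter((m0 + as.integer(x) + 2L * as.integer(y)) %% 5L, alphabet)
}

#' Build a wallpaper grid
#'
#' Generates the rectangular region `x = 0..width-1`, `y = 0..height-1` of the
#' lattice.  Every row reads the cycle E-C-A-T-G; the cell directly above an
#' `E` is `A` (the knight's-move translation of the cruciform motif), and each
#' 5x5 block contains every letter exactly five times.
#'
#' @param width,height Positive integers.
#' @param origin Base letter at `(0, 0)`.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return A `wallpaper_grid` object holding the letter matrix (row 1 is the
#'   top row, i.e. the highest `y`).
#' @export
wallpaper_grid <- function(width, height, origin = "E",
                           alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  width <- as.integer(width)
  height <- as.integer(height)
  if (width < 1L || height < 1L) stop("width and height must be positive")
  cells <- outer(rev(seq_len(height) - 1L), seq_len(width) - 1L,
                 function(y, x) grid_letter(x, y, origin, alphabet))
  structure(list(width = width, height = height, origin = toupper(origin),
                 alphabet = alphabet, cells = cells),
            class = "wallpaper_grid")
}

#' Query a cell of a wallpaper grid
#'
#' @param grid A `wallpaper_grid`.
#' @param x,y Integer coordinates (any integers; computed modularly, so
#'   queries outside the stored region are permitted).
#' @return Character vector of letters.
#' @export
grid_cell <- function(grid, x, y) {
  stopifnot(inherits(grid, "wallpaper_grid"))
  grid_letter(x, y, grid$origin, grid$alphabet)
}

#' @method format wallpaper_grid
#' @export
format.wallpaper_grid <- function(x, ...) {
  apply(x$cells, 1L, paste, collapse = "")
}

#' @export
print.wallpaper_grid <- function(x, ...) {
  cat(sprintf("<wallpaper_grid %dx%d origin %s>\n", x$width, x$height, x$origin))
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Polygonal-line coordinates of a sequence vector
#'
#' One point per explicit entry: `x` is the place number and `y` the phase
#' index (E = 0, C = 1, A = 2, T/U = 3, G = 4).  With
#' `include_implicit = TRUE`, implicit E's inside the explicit span are filled
#' in at `y = 0`.
#'
#' @param s A `seqvec`.
#' @param include_implicit Also emit points for implicit E's up to the last
#'   explicit place (default `FALSE`).
#' @return A data frame with columns `place`, `index`, `letter`, ordered by
#'   place.
#' @export
orbit_path <- function(s, include_implicit = FALSE) {
  stopifnot(inherits(s, "seqvec"))
  place <- s$place
  index <- s$index
  if (include_implicit && length(place)) {
    full <- seq_len(max(place))
    index <- integer(length(full))
    index[match(place, full)] <- s$index
    place <- full
  }
  data.frame(place = place, index = index,
             letter = base_letter(index, s$alphabet))
}

#' Plot a sequence vector as a polygonal line
#'
#' @param s A `seqvec`.
#' @param include_implicit Passed to [orbit_path()].
#' @return A ggplot object with the five index levels labelled by letter.
#' @export
plot_orbit <- function(s, include_implicit = FALSE) {
  pts <- orbit_path(s, include_implicit)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$place, y = .data$index)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(
      breaks = 0:4, limits = c(0, 4),
      labels = paste0(ALPHABETS[[s$alphabet]], " (", 0:4, ")")
    ) +
    ggplot2::labs(x = "place number", y = "base") +
    ggplot2::theme_minimal()
}
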