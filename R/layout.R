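#' Target labels for one part of the Trail Making Test
#'
#' Part A links the numbers 1--25 in ascending order; part B alternates
#' numbers and letters ("1", "A", "2", "B", ..., "13"), 25 items in total.
#'
#' @param part `"A"` or `"B"`.
#' @return Character vector of 25 labels in linking order.
#' @export
tmt_labels <- function(part = c("A", "B")) {
  part <- match.arg(part)
  if (part == "A") {
    as.character(1:25)
  } else {
    out <- character(25)
    out[seq(1, 25, by = 2)] <- as.character(1:13)
    out[seq(2, 24, by = 2)] <- LETTERS[1:12]
    out
  }
}

#' Generate a pseudo-random TMT stimulus layout
#'
#' Places 25 non-overlapping target circles uniformly at random on the
#' canvas by rejection sampling, mimicking the pseudo-random spatial
#' patterns shown on the tablet display. Coordinates are in pixels with the
#' origin at the top-left corner and y increasing downward.
#'
#' @param part `"A"` (numbers 1--25) or `"B"` (alternating numbers/letters).
#' @param canvas Width and height of the display in pixels.
#' @param radius Circle radius in pixels.
#' @param min_sep Minimum gap between circle edges in pixels.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param max_attempts Total rejection-sampling budget before giving up.
#' @return An object of class `tmt_layout`: a list with `part`, `items`
#'   (data frame `label`, `x`, `y` in linking order), `radius`, `canvas`.
#' @export
generate_layout <- function(part = c("A", "B"), canvas = c(1024, 768),
                            radius = 30, min_sep = 10, seed = 1L,
                            max_attempts = 20000L) {
  part <- match.arg(part)
  stopifnot(length(canvas) == 2, all(canvas > 0), radius > 0, min_sep >= 0)
  labels <- tmt_labels(part)
  n <- length(labels)
  if (canvas[1] <= 2 * radius || canvas[2] <= 2 * radius)
    stop("canvas too small to place circles of radius ", radius)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d_min <- 2 * radius + min_sep
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("layout placement failed: rejection budget (", max_attempts,
           " attempts) exhausted; enlarge the canvas or shrink the circles")
    x <- runif(1, radius, canvas[1] - radius)
    y <- runif(1, radius, canvas[2] - radius)
    if (length(xs) == 0L || all(sqrt((xs - x)^2 + (ys - y)^2) > d_min)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  structure(
    list(part = part,
         items = data.frame(label = labels, x = xs, y = ys,
                            stringsAsFactors = FALSE),
         radius = radius, canvas = canvas),
    class = "tmt_layout")
}

#' @export
print.tmt_layout <- function(x, ...) {
  cat(sprintf("TMT part %s layout: %d items, radius %g px, canvas %g x %g px\n",
              x$part, nrow(x$items), x$radius, x$canvas[1], x$canvas[2]))
  invisible(x)
}

# Save/restore the global RNG state so generator functions with explicit
# seeds do not disturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a layout as JSON
#' @param layout A `tmt_layout`.
#' @param path Output file.
#' @return `read_layout` returns a `tmt_layout`.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(
    list(part = layout$part, radius = layout$radius, canvas = layout$canvas,
         items = layout$items),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(part = j$part, items = as.data.frame(j$items),
                 radius = j$radius, canvas = as.numeric(j$canvas)),
            class = "tmt_layout")
}
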