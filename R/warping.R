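#' Dynamic time warping between two series
#'
#' Classic DTW with the symmetric step pattern \{(1,1),(1,0),(0,1)\}, squared
#' local cost and no slope weighting; the reported distance is the square
#' root of the accumulated cost along the optimal path. Ties between
#' equal-cost predecessors are resolved deterministically: diagonal, then
#' vertical (advancing the first series), then horizontal.
#'
#' @param x,y Numeric vectors (lengths may differ).
#' @return A `"warping_result"`: list with `distance` and `path`, a
#'   `"warping_path"` integer matrix with 0-based columns `i` (into `x`) and
#'   `j` (into `y`), starting at (0,0) and ending at (m-1, n-1).
#' @seealso [ldtw()] for the path-length-limited variant used in production.
#' @export
#' @examples
#' dtw(c(0, 1, 2), c(0, 1, 1, 2))$distance  # 0
dtw <- function(x, y) {
  res <- .dtw_cpp(as.numeric(x), as.numeric(y))
  new_warping_result(res$distance, res$path, max_length = NULL)
}

#' DTW under limited warping path length (LDTW)
#'
#' Minimizes the same accumulated squared cost as [dtw()] but only over
#' monotone contiguous warping paths whose number of index pairs does not
#' exceed `max_length`. Limiting the path length suppresses the pathological
#' many-to-one stretches of naive DTW that misalign P- and T-wave endpoints.
#' With `max_length = m + n - 1` the constraint is vacuous and LDTW equals
#' DTW.
#'
#' The solver is an exact dynamic program over states (i, j, path length),
#' O(m n max_length) time, iterated in path-length layers so only two cost
#' layers are held at once.
#'
#' @param x,y Numeric vectors of lengths `m`, `n`.
#' @param max_length Maximum number of index pairs on the path; must be at
#'   least `max(m, n)` (the minimum feasible path length). Values above
#'   `m + n - 1` are clipped. Defaults to [default_max_length()] of `m`.
#' @return A `"warping_result"` as for [dtw()]; the path length never
#'   exceeds `max_length`.
#' @export
#' @examples
#' ldtw(c(0, 0, 1), c(0, 1, 1), max_length = 3)$distance  # 1 (diagonal forced)
#' ldtw(c(0, 0, 1), c(0, 1, 1), max_length = 4)$distance  # 0
ldtw <- function(x, y, max_length = default_max_length(length(x))) {
  m <- length(x)
  n <- length(y)
  max_length <- as.integer(max_length)
  if (max_length < max(m, n)) {
    stop("max_length (", max_length, ") is infeasible: minimum path length is ",
         max(m, n))
  }
  res <- .ldtw_cpp(as.numeric(x), as.numeric(y), max_length)
  new_warping_result(res$distance, res$path, max_length = max_length)
}

#' Default LDTW path-length bound
#'
#' The production setting ties the bound to the series length: `m + 10`
#' (e.g. 410 for the 400-sample beats of a 1600 ms window at 250 Hz).
#' Downstream callers clip it to the vacuous bound `m + n - 1` when that is
#' smaller.
#'
#' @param m Series length (>= 1).
#' @return Integer `m + 10`.
#' @export
default_max_length <- function(m) {
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be >= 1")
  m + 10L
}

new_warping_result <- function(distance, path, max_length = NULL) {
  colnames(path) <- c("i", "j")
  class(path) <- c("warping_path", class(path))
  structure(list(distance = distance, path = path, max_length = max_length),
            class = "warping_result")
}

#' @export
print.warping_result <- function(x, ...) {
  cat(sprintf("warping result: distance %.6f, path length %d%s\n",
              x$distance, nrow(x$path),
              if (is.null(x$max_length)) "" else
                sprintf(" (max_length %d)", x$max_length)))
  invisible(x)
}

#' Validate a warping path
#'
#' Checks boundary conditions (starts at (0,0), ends at (m-1, n-1)),
#' monotone unit steps, and, when given, the path-length bound. Used
#' internally on every returned path and exposed for audits.
#'
#' @param path A `"warping_path"` matrix (0-based columns `i`, `j`).
#' @param m,n Series lengths.
#' @param max_length Optional bound on the number of pairs.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_warping_path <- function(path, m, n, max_length = NULL) {
  if (nrow(path) < 1L) stop("empty warping path")
  if (path[1L, 1L] != 0L || path[1L, 2L] != 0L) stop("path must start at (0,0)")
  if (path[nrow(path), 1L] != m - 1L || path[nrow(path), 2L] != n - 1L) {
    stop("path must end at (m-1, n-1)")
  }
  if (nrow(path) > 1L) {
    di <- diff(path[, 1L])
    dj <- diff(path[, 2L])
    if (any(di < 0L) || any(dj < 0L) || any(di > 1L) || any(dj > 1L) ||
        any(di + dj == 0L)) {
      stop("path steps must increment i, j, or both by exactly 1")
    }
  }
  if (!is.null(max_length) && nrow(path) > max_length) {
    stop("path length ", nrow(path), " exceeds max_length ", max_length)
  }
  invisible(TRUE)
}

#' Write a warping path as a two-column CSV for audit
#'
#' @param path A `"warping_path"` matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_warping_path <- function(path, file) {
  df <- data.frame(template_index = path[, 1L], beat_index = path[, 2L])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
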