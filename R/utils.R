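#' Wrap a phase angle into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped into the principal interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# The 9 one-pixel-shifted copies of a matrix with clamped (edge-replicating)
# borders, as a list; the shared primitive of the 3x3 neighbourhood filters.
.shifted9 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- function(i) pmax(i - 1L, 1L)
  dn <- function(i, n) pmin(i + 1L, n)
  ri <- seq_len(nr); ci <- seq_len(nc)
  list(
    m[ri, ci, drop = FALSE],
    m[up(ri), ci, drop = FALSE], m[dn(ri, nr), ci, drop = FALSE],
    m[ri, up(ci), drop = FALSE], m[ri, dn(ci, nc), drop = FALSE],
    m[up(ri), up(ci), drop = FALSE], m[up(ri), dn(ci, nc), drop = FALSE],
    m[dn(ri, nr), up(ci), drop = FALSE], m[dn(ri, nr), dn(ci, nc), drop = FALSE]
  )
}

# 3x3 median filter with clamped borders, vectorised as a pmin/pmax sorting
# network over the 9 shifted copies. Isolated pixels are removed; a solid
# rectangle keeps its bounding box (interior corners are shaved, border-
# abutting ones kept by the clamping).
median_filter3 <- function(m) {
  stopifnot(is.matrix(m))
  vs <- .shifted9(m)
  for (j in 1:8) {
    for (i in 1:(9 - j)) {
      lo <- pmin(vs[[i]], vs[[i + 1L]])
      vs[[i + 1L]] <- pmax(vs[[i]], vs[[i + 1L]])
      vs[[i]] <- lo
    }
  }
  vs[[5L]]
}

# 3x3 binary dilation / erosion with clamped borders.
dilate3 <- function(mask) Reduce(`|`, .shifted9(mask))
erode3 <- function(mask) Reduce(`&`, .shifted9(mask))

# Label 4-connected components of a logical matrix. Returns an integer matrix
# with 0 for background and 1..k for components (labels in first-encounter
# order, column-major). Vectorised frontier BFS per component.
label_components4 <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  unvisited <- mask
  next_lab <- 0L
  seeds <- which(unvisited)
  for (s in seeds) {
    if (!unvisited[s]) next
    next_lab <- next_lab + 1L
    frontier <- s
    unvisited[s] <- FALSE
    lab[s] <- next_lab
    while (length(frontier) > 0L) {
      r <- (frontier - 1L) %% nr + 1L
      co <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier[co > 1L] - nr, frontier[co < nc] + nr)
      nb <- unique(nb[unvisited[nb]])
      if (length(nb) > 0L) {
        unvisited[nb] <- FALSE
        lab[nb] <- next_lab
      }
      frontier <- nb
    }
  }
  lab
}
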