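# Internal numeric helpers shared across modules.

#' @importFrom stats median mad rnorm runif sd var
NULL

## Relative mass difference in parts per million.
ppmDiff <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Running minimum/maximum over a centered window (van Herk-Gil-Werman):
## O(n) regardless of window width. Even widths are promoted to the next odd.
runExtreme <- function(x, width, op = c("min", "max")) {
  op <- match.arg(op)
  if (width %% 2 == 0) width <- width + 1L
  n <- length(x)
  if (width >= 2L * n) {
    ext <- if (op == "min") min(x) else max(x)
    return(rep(ext, n))
  }
  h <- width %/% 2
  pad <- if (op == "min") Inf else -Inf
  xp <- c(rep(pad, h), x, rep(pad, h))
  m <- length(xp)
  nblk <- ceiling(m / width)
  xp2 <- c(xp, rep(pad, nblk * width - m))
  blk <- matrix(xp2, nrow = width)
  if (op == "min") {
    pref <- apply(blk, 2L, cummin)
    suff <- apply(blk, 2L, function(v) rev(cummin(rev(v))))
  } else {
    pref <- apply(blk, 2L, cummax)
    suff <- apply(blk, 2L, function(v) rev(cummax(rev(v))))
  }
  pref <- as.vector(pref)
  suff <- as.vector(suff)
  i <- seq_len(n)
  if (op == "min") pmin(suff[i], pref[i + width - 1L])
  else pmax(suff[i], pref[i + width - 1L])
}

## 0-based pixel coordinates -> grid dimensions (rows, cols).
gridDims <- function(coords) {
  c(rows = max(coords[, "y"]) + 1L, cols = max(coords[, "x"]) + 1L)
}

## Fill a rows x cols matrix (NA background) from per-pixel values.
valuesToGrid <- function(values, coords) {
  dims <- gridDims(coords)
  grid <- matrix(NA_real_, nrow = dims["rows"], ncol = dims["cols"])
  grid[cbind(coords[, "y"] + 1L, coords[, "x"] + 1L)] <- values
  grid
}

## Extract per-pixel values back out of a grid.
gridToValues <- function(grid, coords) {
  grid[cbind(coords[, "y"] + 1L, coords[, "x"] + 1L)]
}

## Normalize a coords input (matrix or data.frame with x, y) to an
## integer matrix with columns x, y.
asCoords <- function(coords) {
  coords <- as.matrix(coords)
  if (is.null(colnames(coords)) || !all(c("x", "y") %in% colnames(coords))) {
    if (ncol(coords) != 2L)
      stop("coords must have two columns (x, y)")
    colnames(coords) <- c("x", "y")
  }
  storage.mode(coords) <- "integer"
  coords[, c("x", "y"), drop = FALSE]
}
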