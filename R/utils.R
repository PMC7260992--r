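# Internal helpers: seeding, raster shifts, connected components, small
# geometry utilities. Nothing here is exported except deriveSeed and
# labelComponents, which users of the synthetic generator may want directly.

#' Derive a stage seed from a master seed
#'
#' Hashes the master seed together with an arbitrary sequence of string/number
#' tokens into a 32-bit seed, so that every stochastic stage of the pipeline
#' consumes its own reproducible seed regardless of execution order.
#'
#' @param seed integer master seed.
#' @param ... tokens naming the stage (coerced to character).
#' @return An integer in [0, 2^31).
#' @examples
#' deriveSeed(1, "bootstrap", "P03", "A2")
#' @export
deriveSeed <- function(seed, ...) {
  toks <- paste(c(as.character(seed),
                  vapply(list(...), as.character, character(1))),
                collapse = "/")
  h <- 0
  for (k in utf8ToInt(toks)) h <- (h * 31 + k) %% 2147483629
  as.integer(h)
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# result[r, c] = m[r - dr, c - dc], replicating edges.
shiftMat <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) - dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) - dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# result[r, c] = m[r - dr, c - dc], zero-filled outside.
shiftMat0 <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rok <- rs - dr >= 1L & rs - dr <= nrow(m)
  cok <- cs - dc >= 1L & cs - dc <= ncol(m)
  out[rs[rok], cs[cok]] <- m[rs[rok] - dr, cs[cok] - dc]
  out
}

# 3x3 mean filter with replicated borders.
boxBlur3 <- function(m) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) acc <- acc + shiftMat(m, dr, dc)
  acc / 9
}

# Diamond (city-block disk) structuring element of radius r; radius 1 is the
# 3x3 plus shape.
diamondKernel <- function(r) {
  s <- 2L * r + 1L
  d <- abs(outer(seq_len(s) - r - 1L, seq_len(s) - r - 1L, function(a, b) abs(a) + abs(b)))
  matrix(as.numeric(d <= r), s, s)
}

# Euclidean disk structuring element of radius r (odd-sized).
diskKernel <- function(r) {
  s <- 2L * r + 1L
  d2 <- outer((seq_len(s) - r - 1L)^2, (seq_len(s) - r - 1L)^2, `+`)
  matrix(as.numeric(d2 <= r^2 + 1e-9), s, s)
}

#' Label connected components
#'
#' Labels foreground components of a binary raster with 8- (default) or
#' 4-connectivity. Labels are consecutive integers assigned in column-major
#' order of first appearance, so labeling is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix, 0 = background.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1)  # 4-connected
  lab <- matrix(as.integer(round(lab)), nrow(mask))
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1L) {
    parent <- seq_len(nlab)
    findRoot <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    for (sh in list(c(1L, 1L), c(1L, -1L))) {
      a <- lab[seq_len(nrow(lab) - 1L),
               if (sh[2] > 0) seq_len(ncol(lab) - 1L) else -1L, drop = FALSE]
      b <- lab[-1L,
               if (sh[2] > 0) -1L else seq_len(ncol(lab) - 1L), drop = FALSE]
      sel <- which(a > 0L & b > 0L & a != b)
      for (i in sel) {
        ra <- findRoot(a[i]); rb <- findRoot(b[i])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(nlab), findRoot, integer(1))
    pos <- lab > 0L
    lab[pos] <- roots[lab[pos]]
  }
  pos <- lab > 0L
  if (any(pos)) lab[pos] <- match(lab[pos], unique(lab[pos]))
  lab
}

# Min-max normalize to [0, 1]; constant input returns NULL.
normalize01 <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) return(NULL)
  (x - r[1]) / diff(r)
}

# Shoelace area of a polygon given as a two-column matrix.
polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Skewness (moment estimator m3 / sd^3); NA for n < 3 or zero spread.
momentSkewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  mean((x - mean(x))^3) / s^3
}
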