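#' @importFrom stats fft median quantile sd var cor shapiro.test t.test
#'   wilcox.test oneway.test rnorm complete.cases setNames p.adjust
#' @importFrom utils read.csv write.csv head tail
NULL

# Shift a matrix by (di, dj) with edge replication (used by flow smoothing
# and finite differences).
shift_mat <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- pmin(pmax(seq_len(n1) - di, 1L), n1)
  j <- pmin(pmax(seq_len(n2) - dj, 1L), n2)
  m[i, j, drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' 4-connected components labelled in deterministic raster-scan order
#' (column-major, matching R's array layout): the component containing the
#' first foreground voxel encountered gets label 1, and so on.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- integer(256L); queue[1L] <- start; qh <- 1L; qt <- 1L
    lab[start] <- nxt
    while (qh <= qt) {
      cur <- queue[qh]; qh <- qh + 1L
      i <- ((cur - 1L) %% n1) + 1L
      j <- ((cur - 1L) %/% n1) + 1L
      for (k in 1:4) {
        ni <- i + c(-1L, 1L, 0L, 0L)[k]
        nj <- j + c(0L, 0L, -1L, 1L)[k]
        if (ni < 1L || ni > n1 || nj < 1L || nj > n2) next
        nb <- (nj - 1L) * n1 + ni
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- nxt
          qt <- qt + 1L
          if (qt > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qt] <- nb
        }
      }
    }
  }
  lab
}

# Keep the k largest components (by voxel count) of a logical mask.
keep_largest_components <- function(mask, k = 1L, min_area = 1L) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(k, length(sizes)))]
  keep <- keep[sizes[keep] >= min_area]
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Bilinear sampling of `img` at arbitrary coordinate matrices (ii, jj);
# coordinates are clamped to the image so border values are replicated.
sample_bilinear <- function(img, ii, jj) {
  n1 <- nrow(img); n2 <- ncol(img)
  out_dim <- dim(ii)
  ii <- pmin(pmax(ii, 1), n1)
  jj <- pmin(pmax(jj, 1), n2)
  i0 <- pmin(floor(ii), n1 - 1L); j0 <- pmin(floor(jj), n2 - 1L)
  di <- ii - i0; dj <- jj - j0
  idx <- function(i, j) (j - 1L) * n1 + i
  w00 <- img[idx(i0, j0)]; w10 <- img[idx(i0 + 1L, j0)]
  w01 <- img[idx(i0, j0 + 1L)]; w11 <- img[idx(i0 + 1L, j0 + 1L)]
  out <- (1 - di) * (1 - dj) * w00 + di * (1 - dj) * w10 +
    (1 - di) * dj * w01 + di * dj * w11
  matrix(out, out_dim[1], out_dim[2])
}

# Pull-back warp: value at voxel (i, j) sampled from img at (i + u, j + v).
warp_bilinear <- function(img, u, v) {
  n1 <- nrow(img); n2 <- ncol(img)
  ii <- matrix(seq_len(n1), n1, n2) + u
  jj <- matrix(seq_len(n2), n1, n2, byrow = TRUE) + v
  sample_bilinear(img, ii, jj)
}

# Nearest-neighbour sampling (for masks).
warp_nearest <- function(img, u, v) {
  n1 <- nrow(img); n2 <- ncol(img)
  ii <- round(matrix(seq_len(n1), n1, n2) + u)
  jj <- round(matrix(seq_len(n2), n1, n2, byrow = TRUE) + v)
  ii <- pmin(pmax(ii, 1L), n1)
  jj <- pmin(pmax(jj, 1L), n2)
  matrix(img[(jj - 1L) * n1 + ii], n1, n2)
}

# Analytic signal (FFT construction): x + i * H(x). Used for instantaneous
# cardiac phase.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Evaluate an expression with a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
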