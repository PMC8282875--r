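#' @useDynLib msmseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reflected (edge-inclusive) index folding: maps arbitrary integer i onto
# 1..n as  ... 3 2 1 | 1 2 3 ... n | n n-1 ...  Works for any pad width.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Pad a matrix by reflection (edge pixel repeated, scipy 'reflect' dialect).
pad_reflect <- function(m, p) {
  if (p == 0L) return(m)
  ri <- reflect_index(seq_len(nrow(m) + 2L * p) - p, nrow(m))
  ci <- reflect_index(seq_len(ncol(m) + 2L * p) - p, ncol(m))
  m[ri, ci, drop = FALSE]
}

# Neighbour view: m shifted by (di, dj) with reflected borders, same shape.
# out[i, j] = m[i + di, j + dj].
shift_reflect <- function(m, di, dj) {
  ri <- reflect_index(seq_len(nrow(m)) + di, nrow(m))
  ci <- reflect_index(seq_len(ncol(m)) + dj, ncol(m))
  m[ri, ci, drop = FALSE]
}

# True 2D convolution (kernel flipped) with reflected borders.
conv2_reflect <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kernel[a, b]
      if (w == 0) next
      # convolution: out(i,j) += k(a,b) * img(i - (a - cr), j - (b - cc))
      out <- out + w * shift_reflect(img, -(a - pr - 1L), -(b - pc - 1L))
    }
  }
  out
}

clip255 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
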