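# Independent brute-force oracles used across tests. Deliberately naive:
# double loops and direct definitions, no shared code with the package
# internals they check.

# min/max filter with a centred k x k square and edge replication
brute_minmax <- function(img, k, do_max) {
  r <- k %/% 2
  n <- nrow(img); m <- ncol(img)
  out <- img
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ii <- max(1, i - r):min(n, i + r)
    jj <- max(1, j - r):min(m, j + r)
    out[i, j] <- if (do_max) max(img[ii, jj]) else min(img[ii, jj])
  }
  out
}

brute_close <- function(img, k) brute_minmax(brute_minmax(img, k, TRUE), k, FALSE)
brute_open <- function(img, k) brute_minmax(brute_minmax(img, k, FALSE), k, TRUE)

# Euclidean distance to the nearest TRUE pixel, by direct minimisation
brute_edt <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
  out
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# filled disk mask
disk_mask <- function(n, cy, cx, r) {
  (row(matrix(0, n, n)) - cy)^2 + (col(matrix(0, n, n)) - cx)^2 <= r^2
}
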