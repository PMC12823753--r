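# Independent brute-force oracles: straightforward pixel/pair enumeration,
# deliberately kept free of the package's vectorized code paths.

brute_confusion <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- isTRUE(pred[i, j]); r <- isTRUE(ref[i, j])
      if (p && r) tp <- tp + 1L
      else if (p && !r) fp <- fp + 1L
      else if (!p && r) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

brute_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  at <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && isTRUE(mask[i, j])
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!isTRUE(mask[i, j])) next
      if (!at(i - 1, j) || !at(i + 1, j) || !at(i, j - 1) || !at(i, j + 1)) {
        out[i, j] <- TRUE
      }
    }
  }
  out
}

# O(n^2) directed surface distances: for each boundary pixel of `from`, the
# minimum Euclidean distance to any boundary pixel of `to`.
brute_directed_distances <- function(from_mask, to_mask) {
  fb <- which(brute_boundary(from_mask), arr.ind = TRUE)
  tb <- which(brute_boundary(to_mask), arr.ind = TRUE)
  out <- numeric(nrow(fb))
  for (k in seq_len(nrow(fb))) {
    best <- Inf
    for (l in seq_len(nrow(tb))) {
      d <- sqrt((fb[k, 1] - tb[l, 1])^2 + (fb[k, 2] - tb[l, 2])^2)
      if (d < best) best <- d
    }
    out[k] <- best
  }
  out
}

brute_band <- function(mask, d) {
  b <- which(brute_boundary(mask), arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!isTRUE(mask[i, j])) next
      for (k in seq_len(nrow(b))) {
        if (sqrt((i - b[k, 1])^2 + (j - b[k, 2])^2) <= d) {
          out[i, j] <- TRUE
          break
        }
      }
    }
  }
  out
}

# Closed-form Spearman for untied data.
spearman_untied <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Blobby random mask: union of a few disks plus salt noise, so boundaries
# are non-trivial but not space-filling.
random_blob_mask <- function(h, w, n_disks = sample(1:3, 1)) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_disks)) {
    r <- runif(1, 2, min(h, w) / 4)
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    m <- m | ((rows - cy)^2 + (cols - cx)^2 <= r^2)
  }
  salt <- matrix(runif(h * w) < 0.01, h, w)
  out <- xor(m, salt)
  if (!any(out)) out[sample(h, 1), sample(w, 1)] <- TRUE
  out
}

square_mask <- function(h, w, r1, r2, c1, c2) {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1:c2] <- TRUE
  m
}
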