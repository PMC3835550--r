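# Independent brute-force reference implementations used to cross-check
# the package's fast paths. Deliberately naive: direct loops, sort-based
# medians, recursive-free flood fill.

# 1-based edge-inclusive mirror reflection with period 2n.
reflect_index_oracle <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2 * n
  i <- ((i - 1) %% p) + 1
  ifelse(i <= n, i, p - i + 1)
}

# m x m median filter by explicit window extraction; stats::median gives
# the mean of the two middle order statistics for even counts.
median_filter_oracle <- function(x, m) {
  n <- nrow(x); r <- ncol(x)
  lo <- -(m %/% 2)
  offs <- lo:(lo + m - 1)
  out <- matrix(0, n, r)
  for (i in seq_len(n)) {
    ri <- reflect_index_oracle(i + offs, n)
    for (j in seq_len(r)) {
      ci <- reflect_index_oracle(j + offs, r)
      out[i, j] <- stats::median(as.vector(x[ri, ci]))
    }
  }
  out
}

# Stack-based flood fill labelling.
label_oracle <- function(mask, connectivity) {
  n <- nrow(mask); r <- ncol(mask)
  lab <- matrix(0L, n, r)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  nxt <- 0L
  for (j in seq_len(r)) for (i in seq_len(n)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- matrix(c(i, j), 1, 2)
    lab[i, j] <- nxt
    while (nrow(stack) > 0) {
      q <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_along(dr)) {
        ni <- q[1] + dr[k]; nj <- q[2] + dc[k]
        if (ni >= 1 && ni <= n && nj >= 1 && nj <= r &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          stack <- rbind(stack, c(ni, nj))
        }
      }
    }
  }
  lab
}

# Canonical form of a labelling: relabel by first occurrence in
# column-major order, so two labelings of the same partition compare
# equal regardless of label assignment order.
canonical_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  map <- integer(max(c(0L, ids)))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

random_mask <- function(n, r, p = 0.35) {
  matrix(stats::runif(n * r) < p, n, r)
}

random_image <- function(n, r) {
  matrix(stats::runif(n * r), n, r)
}
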