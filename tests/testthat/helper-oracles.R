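# Independent brute-force oracles used across the suite.

# Stack-based flood fill over an explicit neighbour offset table.
flood_fill_labels <- function(mask, connectivity = "face") {
  dims <- dim(mask)
  max_l1 <- switch(connectivity, face = 1L, edge = 2L, corner = 3L)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) >= 1 & rowSums(abs(offs)) <= max_l1, , drop = FALSE]
  labels <- array(0L, dims)
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(v, dims)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1L) || any(nb > dims)) next
        if (mask[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- lab
          stack <- c(stack, (nb[3] - 1L) * dims[1] * dims[2] +
                       (nb[2] - 1L) * dims[1] + nb[1])
        }
      }
    }
  }
  labels
}

# Partition of voxel sets induced by a labelling (for label-agnostic compare).
partition_sets <- function(labels) {
  idx <- which(labels > 0L)
  unname(lapply(split(idx, labels[idx]), sort))
}

same_partition <- function(a, b) {
  pa <- partition_sets(a)
  pb <- partition_sets(b)
  setequal(lapply(pa, paste, collapse = ","), lapply(pb, paste, collapse = ","))
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments.
wilcoxon_exact_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% rk)
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Random orthogonal matrix (QR of a Gaussian matrix, sign-fixed).
random_orthogonal <- function(k) {
  qr_ <- qr(matrix(rnorm(k * k), k, k))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), k)
}
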