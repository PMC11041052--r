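# Independent pure-R oracles used to cross-check the C++ morphology and
# network kernels. Deliberately simple and slow: flood fill over linear
# indices, exhaustive neighbourhood scans.

.offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(off))
  keep <- m > 0 & switch(as.character(connectivity),
                         "6" = m <= 1, "18" = m <= 2, "26" = TRUE)
  off[keep, , drop = FALSE]
}

# Flood-fill connected components, background = 0.
bruteComponents <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- .offsets(connectivity)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    lab[s] <- nxt
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      z <- (v - 1L) %/% (d[1] * d[2])
      rem <- (v - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1]
      x <- rem %% d[1]
      for (k in seq_len(nrow(off))) {
        nx <- x + off[k, 1]; ny <- y + off[k, 2]; nz <- z + off[k, 3]
        if (nx < 0 || nx >= d[1] || ny < 0 || ny >= d[2] ||
            nz < 0 || nz >= d[3]) next
        u <- 1L + nx + d[1] * (ny + d[2] * nz)
        if (mask[u] != 0 && lab[u] == 0L) {
          lab[u] <- nxt
          stack <- c(stack, u)
        }
      }
    }
  }
  lab
}

# For each component id in lab, does any voxel neighbour `other`?
bruteTouches <- function(lab, other, connectivity = 26) {
  d <- dim(lab)
  off <- .offsets(connectivity)
  k <- max(lab)
  if (k == 0L) return(logical(0))
  touch <- logical(k)
  idx <- which(lab > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    id <- lab[idx[r, 1], idx[r, 2], idx[r, 3]]
    if (touch[id]) next
    for (j in seq_len(nrow(off))) {
      nb <- idx[r, ] + off[j, ]
      if (any(nb < 1) || any(nb > d)) next
      if (other[nb[1], nb[2], nb[3]] != 0) {
        touch[id] <- TRUE
        break
      }
    }
  }
  touch
}

# A random sparse 3-class label volume for filter cross-checks.
randomLabelVolume <- function(seed, d = c(20, 20, 20),
                              p = c(0.88, 0.07, 0.05)) {
  withr::with_seed(seed,
    array(sample(0:2, prod(d), replace = TRUE, prob = p), d))
}

# Small phantom spec used across tests (fast to generate).
testPhantomSpec <- function(seed = 1L, nCysts = 1L, ...) {
  phantomSpec(gridShape = c(48L, 48L, 32L), spacing = c(1.5, 1.5, 5),
              nCysts = nCysts, cystRadiusRange = c(2.5, 4), seed = seed, ...)
}
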