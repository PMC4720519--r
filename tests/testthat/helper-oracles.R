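# Independent brute-force oracles used across tests. These deliberately use
# naive exhaustive computations so they stay independent of the package's
# implementation paths.

# exhaustive sliding-window baseline
oracle_baseline <- function(f, n_win) {
  means <- sapply(seq_len(length(f) - n_win + 1), function(i) {
    w <- f[i:(i + n_win - 1)]
    mean(w[is.finite(w)])
  })
  min(means, na.rm = TRUE)
}

# exhaustive peak finder: local maxima above the absolute threshold whose
# rise from the trough since the last accepted peak also reaches the
# threshold, scanned in time order with a minimum apex separation
oracle_peaks <- function(x, t, thr, min_sep) {
  n <- length(x)
  if (n < 2) return(integer(0))
  cand <- c()
  for (i in seq_len(n)) {
    lo <- if (i == 1) TRUE else x[i] > x[i - 1]
    hi <- if (i == n) TRUE else x[i] >= x[i + 1]
    if (lo && hi && x[i] >= thr) cand <- c(cand, i)
  }
  kept <- c()
  for (i in cand) {
    if (length(kept) == 0) {
      if (x[i] - min(x[1:i]) >= thr) kept <- i
      next
    }
    prev <- kept[length(kept)]
    seg_min <- min(x[prev:i])
    rearmed <- (x[prev] - seg_min) >= 0.5 * thr
    if (rearmed && t[i] - t[prev] >= min_sep && x[i] - seg_min >= thr) {
      kept <- c(kept, i)
    } else if (!rearmed && x[i] > x[prev]) {
      kept[length(kept)] <- i
    }
  }
  kept
}

# exhaustive scan of voxels inside a physical sphere
oracle_sphere_max <- function(volume, vox_zyx, center_xyz, diameter) {
  d <- dim(volume)
  best <- NA_real_
  r2 <- (diameter / 2)^2
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    dz <- (z - 1) * vox_zyx[1] - center_xyz[3]
    dy <- (y - 1) * vox_zyx[2] - center_xyz[2]
    dx <- (x - 1) * vox_zyx[3] - center_xyz[1]
    if (dz^2 + dy^2 + dx^2 <= r2) {
      v <- volume[z, y, x]
      if (is.na(best) || v > best) best <- v
    }
  }
  best
}

# exhaustive pairwise-lag synchrony percentages
oracle_synchrony_pct <- function(a, b, win) {
  if (length(a) == 0) return(NA_real_)
  syn <- sapply(a, function(t) {
    if (length(b) == 0) FALSE else min(abs(b - t)) <= win
  })
  100 * mean(syn)
}

# exhaustive region lookup over all thirds of all intervals
oracle_region <- function(x, boundaries) {
  boundaries <- sort(boundaries)
  for (i in seq_len(length(boundaries) - 1)) {
    left <- boundaries[i]; right <- boundaries[i + 1]
    L <- right - left
    for (r in 1:3) {
      lo <- left + (r - 1) * L / 3
      hi <- left + r * L / 3
      inside <- if (r == 3 && i == length(boundaries) - 1) {
        x >= lo && x <= hi   # global right edge closes the last third
      } else {
        x >= lo && x < hi
      }
      if (inside) return(r)
    }
  }
  NA_integer_
}

# exhaustive minimum-total-distance assignment between two small point sets,
# with gating; returns match vector like the package's internal solver
oracle_assignment <- function(a, b, max_cost) {
  n <- nrow(a); m <- nrow(b)
  best <- NULL; best_cost <- Inf
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  # enumerate all partial injections from rows of a into columns of b
  assignments <- list(rep(NA_integer_, n))
  for (i in seq_len(n)) {
    nxt <- list()
    for (as in assignments) {
      nxt[[length(nxt) + 1]] <- as
      for (j in seq_len(m)) {
        if (!(j %in% as) && cost(i, j) <= max_cost) {
          as2 <- as; as2[i] <- j
          nxt[[length(nxt) + 1]] <- as2
        }
      }
    }
    assignments <- nxt
  }
  for (as in assignments) {
    matched <- which(!is.na(as))
    cc <- sum(vapply(matched, function(i) cost(i, as[i]), numeric(1))) +
      max_cost * 1.0000001 * (sum(is.na(as)) + (m - sum(!is.na(as))))
    if (cc < best_cost - 1e-12) {
      best_cost <- cc; best <- as
    }
  }
  best
}
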