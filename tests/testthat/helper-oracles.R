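# Brute-force oracles: every one is a plain scalar loop (or exhaustive
# enumeration), independent of the vectorized implementations it checks.

rand_img <- function(h, w, max_val = 255) {
  matrix(as.double(sample.int(max_val + 1L, h * w, replace = TRUE) - 1L), h, w)
}

rand_mask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# neighborhood rank scan with edge replication (coordinate clamping)
oracle_rank <- function(m, offsets, fun) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- pmin(pmax(i + offsets[, 1], 1L), h)
      jj <- pmin(pmax(j + offsets[, 2], 1L), w)
      out[i, j] <- fun(m[cbind(ii, jj)])
    }
  }
  out
}

oracle_smooth <- function(m) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  oracle_rank(m, offs, sum) / 9
}

oracle_sobel <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      gx <- 0
      gy <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          v <- m[min(max(i + di, 1L), h), min(max(j + dj, 1L), w)]
          gx <- gx + kx[di + 2, dj + 2] * v
          gy <- gy + kx[dj + 2, di + 2] * v
        }
      }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

oracle_gray <- function(r, g, b) {
  out <- matrix(0, nrow(r), ncol(r))
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(ncol(r))) {
      out[i, j] <- 0.299 * r[i, j] + 0.587 * g[i, j] + 0.114 * b[i, j]
    }
  }
  out
}

oracle_edt <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  bg <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 1) {
        out[i, j] <- if (nrow(bg)) {
          sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
        } else {
          sqrt(h * h + w * w + 1)
        }
      }
    }
  }
  out
}

# intermeans fixed point recomputed directly on the pixel values
oracle_isodata <- function(values) {
  thr <- mean(values)
  repeat {
    lo <- values[values <= thr]
    hi <- values[values > thr]
    if (!length(lo) || !length(hi)) {
      return(thr)
    }
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (abs(new_thr - thr) < 1e-9) {
      return(new_thr)
    }
    thr <- new_thr
  }
}

# flood-fill labeling; returns a partition (labels arbitrary)
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8) {
    as.matrix(expand.grid(di = -1:1, dj = -1:1))[-5, ]
  } else {
    cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 1 && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        stack <- list(c(i, j))
        lab[i, j] <- nxt
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (k in seq_len(nrow(offs))) {
            ii <- p[1] + offs[k, 1]
            jj <- p[2] + offs[k, 2]
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
              mask[ii, jj] == 1 && lab[ii, jj] == 0L) {
              lab[ii, jj] <- nxt
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition of the foreground
same_partition <- function(a, b) {
  fa <- a[a > 0 | b > 0]
  fb <- b[a > 0 | b > 0]
  if (any(fa == 0) || any(fb == 0)) {
    return(FALSE)
  }
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}

# rasterized disk mask
draw_disks <- function(h, w, centers, radius) {
  m <- matrix(0L, h, w)
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radius^2) {
          m[i, j] <- 1L
        }
      }
    }
  }
  m
}

# exhaustive best one-to-one matching (max cardinality) on small point sets
oracle_match_count <- function(det, tru, radius) {
  nd <- nrow(det)
  nt <- nrow(tru)
  if (nd == 0 || nt == 0) {
    return(0L)
  }
  dmat <- sqrt(outer(det[, 1], tru[, 1], "-")^2 + outer(det[, 2], tru[, 2], "-")^2)
  ok <- dmat <= radius
  best <- 0L
  assign_next <- function(d, used_t, count) {
    if (count + (nd - d + 1) <= best) {
      return(invisible())
    }
    if (d > nd) {
      best <<- max(best, count)
      return(invisible())
    }
    assign_next(d + 1L, used_t, count) # leave detection d unmatched
    for (t in seq_len(nt)) {
      if (!used_t[t] && ok[d, t]) {
        used_t[t] <- TRUE
        assign_next(d + 1L, used_t, count + 1L)
        used_t[t] <- FALSE
      }
    }
  }
  assign_next(1L, logical(nt), 0L)
  best
}
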