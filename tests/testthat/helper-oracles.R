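# Independent brute-force oracles, deliberately written with plain loops and
# no shared code with the package internals.

# flood-fill connected component labelling at 4- or 8-connectivity
oracle_label <- function(binary, connectivity = 8) {
  m <- binary != 0
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {      # row-major scan
    if (m[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r, c))
      lab[r, c] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              m[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  list(labels = lab, patch_count = cur)
}

# exhaustive Otsu: scan every histogram cut, recompute class weights/means
# per pixel, keep the lowest cut maximising between-class variance
oracle_otsu <- function(block, n_bins = 256) {
  v <- as.vector(block)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(list(threshold = NA_real_, degenerate = TRUE))
  bins <- floor(n_bins * (v - lo) / (hi - lo))
  bins[bins == n_bins] <- n_bins - 1
  best_k <- NA; best_var <- -Inf
  for (k in 1:(n_bins - 1)) {
    left <- bins[bins < k]; right <- bins[bins >= k]
    if (length(left) == 0 || length(right) == 0) next
    w0 <- length(left) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(right) - mean(left))^2
    if (bcv > best_var + 1e-12) { best_var <- bcv; best_k <- k }
  }
  list(threshold = lo + best_k * (hi - lo) / n_bins, degenerate = FALSE)
}

# naive double-loop GLCM + feature evaluation
oracle_glcm_feature <- function(q, dx, dy, levels, symmetric, which,
                                homogeneity_form = "inverse_diff_moment") {
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
      if (symmetric)
        counts[q[r2, c2] + 1, q[r, c] + 1] <- counts[q[r2, c2] + 1, q[r, c] + 1] + 1
    }
  }
  p <- counts / sum(counts)
  val <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    val <- val + switch(which,
      energy = p[i, j]^2,
      contrast = (i - j)^2 * p[i, j],
      homogeneity = if (homogeneity_form == "inverse_diff_moment")
        p[i, j] / (1 + (i - j)^2) else p[i, j] / (1 + abs(i - j)))
  }
  val
}

# exact two-sided Mann-Whitney p by enumerating every way to assign the
# pooled ranks to the first sample
oracle_mw_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# power-iteration largest singular value (independent of svd())
oracle_leading_sv <- function(m, iters = 500) {
  a <- t(m) %*% m
  v <- rep(1, ncol(m))
  for (i in seq_len(iters)) { v <- a %*% v; v <- v / sqrt(sum(v^2)) }
  sqrt(as.numeric(t(v) %*% a %*% v))
}

# small random test block with a few intensity plateaus plus noise
random_block <- function(h, w, levels_hint = 6) {
  base <- sample(0:levels_hint, h * w, replace = TRUE) * 10
  matrix(base + round(runif(h * w, 0, 4)), h, w)
}
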