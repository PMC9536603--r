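# Independent brute-force oracles: plain per-pixel / per-entry loops that
# re-derive every matrix and statistic from first principles. They share
# no code with the package implementation beyond base R.

oracle_envelope <- function(samples, depth, dec) {
  n_lines <- nrow(samples)
  out <- matrix(0, depth %/% dec, n_lines)
  for (l in seq_len(n_lines)) {
    for (i in seq_len(depth %/% dec)) {
      block <- samples[l, ((i - 1) * dec + 1):(i * dec)]
      out[i, l] <- max(abs(block))
    }
  }
  out
}

oracle_glcm <- function(q, angle, L, d = 1L, symmetric = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  counts <- matrix(0, L, L)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  contrast <- 0; energy <- 0; homogeneity <- 0
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum((0:(L - 1)) * px); mu_y <- sum((0:(L - 1)) * py)
  sd_x <- sqrt(sum(((0:(L - 1)) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((0:(L - 1)) - mu_y)^2 * py))
  num <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- P[i + 1, j + 1]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    homogeneity <- homogeneity + p / (1 + (i - j)^2)
    num <- num + (i - mu_x) * (j - mu_y) * p
  }
  list(contrast = contrast,
       correlation = if (sd_x * sd_y > 0) num / (sd_x * sd_y) else 0,
       energy = energy, homogeneity = homogeneity)
}

oracle_sobel <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  at <- function(r, c) px[min(max(r, 1), nr), min(max(c, 1), nc)]
  g <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gx <- (at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
          (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))
    gy <- (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1)) -
          (at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1))
    g[r, c] <- sqrt(gx^2 + gy^2)
  }
  g
}

oracle_ggcm <- function(px, Lg, Ls) {
  gmag <- oracle_sobel(px)
  gmax <- max(gmag)
  H <- matrix(0, Lg, Ls)
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px))) {
    i <- floor(px[r, c] * Lg / 256)
    j <- if (gmax > 0) floor(gmag[r, c] / gmax * (Ls - 1) + 0.5) else 0
    H[i + 1, j + 1] <- H[i + 1, j + 1] + 1
  }
  H
}

oracle_ggcm_features <- function(H) {
  total <- sum(H)
  Lg <- nrow(H); Ls <- ncol(H)
  Hi <- rowSums(H); Hj <- colSums(H)
  small <- 0; large <- 0
  for (j in 0:(Ls - 1)) {
    small <- small + Hj[j + 1] / (1 + j)^2
    large <- large + Hj[j + 1] * j^2
  }
  pi_ <- Hi / total; pj_ <- Hj / total
  mu_i <- sum((0:(Lg - 1)) * pi_); mu_j <- sum((0:(Ls - 1)) * pj_)
  sd_i <- sqrt(sum(((0:(Lg - 1)) - mu_i)^2 * pi_))
  sd_j <- sqrt(sum(((0:(Ls - 1)) - mu_j)^2 * pj_))
  energy <- 0; corr_num <- 0; hyb <- 0; inertia <- 0; idm <- 0
  for (i in 0:(Lg - 1)) for (j in 0:(Ls - 1)) {
    p <- H[i + 1, j + 1] / total
    energy <- energy + p^2
    corr_num <- corr_num + (i - mu_i) * (j - mu_j) * p
    if (p > 0) hyb <- hyb - p * log2(p)
    inertia <- inertia + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
  }
  gent <- 0
  for (j in seq_len(Ls)) if (pj_[j] > 0) gent <- gent - pj_[j] * log2(pj_[j])
  list(small_gradient = small / total,
       large_gradient = large / total,
       gray_nonuniformity = sum(Hi^2) / total,
       gradient_nonuniformity = sum(Hj^2) / total,
       energy = energy,
       mean_gradient = mu_j,
       gradient_msd = sd_j,
       correlation = if (sd_i * sd_j > 0) corr_num / (sd_i * sd_j) else 0,
       gradient_entropy = gent,
       hybrid_entropy = hyb,
       inertia = inertia,
       inverse_difference = idm)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

random_patch <- function(seed, size = 16L, levels = 256L) {
  set.seed(seed)
  matrix(sample.int(levels, size * size, replace = TRUE) - 1L, size, size)
}
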