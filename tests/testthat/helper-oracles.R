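# Independent oracles, deliberately naive: brute force, enumeration, or
# plain coordinate descent run to convergence. These never share code with
# the implementation paths they check.

# cyclic coordinate descent for
# (1/2n)||y - w0 - Xw||^2 + a*r*||w||_1 + a*(1-r)/2*||w||_2^2
oracle_elastic_net <- function(X, y, alpha, rho, max_iter = 20000L,
                               tol = 1e-13) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  w <- rep(0, p)
  w0 <- mean(y)
  xss <- colMeans(X^2)
  for (it in seq_len(max_iter)) {
    w_prev <- w
    w0_prev <- w0
    w0 <- mean(y - X %*% w)
    for (j in seq_len(p)) {
      r_j <- y - w0 - X[, -j, drop = FALSE] %*% w[-j]
      z <- mean(X[, j] * r_j)
      den <- xss[j] + alpha * (1 - rho)
      w[j] <- if (den <= 0) 0 else {
        s <- abs(z) - alpha * rho
        if (s <= 0) 0 else sign(z) * s / den
      }
    }
    if (max(abs(c(w - w_prev, w0 - w0_prev))) < tol) break
  }
  list(w0 = w0, w = w)
}

# direct formula evaluation with explicit loops
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  2 * cxy / (vx + vy + (mx - my)^2)
}

oracle_rmse <- function(x, y) {
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  sqrt(acc / length(x))
}

# per-base membership: exon data.frame (1-based closed) + probe data.frame
# (1-based closed); fraction = sum over transcripts of covered/total bases
oracle_effective_fraction <- function(exons, probes) {
  probe_bases <- unlist(lapply(seq_len(nrow(probes)), function(i) {
    paste0(probes$chrom[i], ":", seq(probes$start[i], probes$end[i]))
  }))
  probe_bases <- unique(probe_bases)
  genes <- unique(exons$gene_id)
  out <- numeric(0)
  for (g in genes) {
    gex <- exons[exons$gene_id == g, ]
    tot <- 0
    cov <- 0
    for (tx in unique(gex$transcript_id)) {
      tex <- gex[gex$transcript_id == tx, ]
      bases <- unique(unlist(lapply(seq_len(nrow(tex)), function(i) {
        paste0(tex$chrom[i], ":", seq(tex$start[i], tex$end[i]))
      })))
      tot <- tot + length(bases)
      cov <- cov + sum(bases %in% probe_bases)
    }
    out[g] <- cov / tot
  }
  out
}

# exhaustive two-sided signed-rank p-value over all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  total <- sum(rk)
  vs <- numeric(2^n)
  for (m in seq_len(2^n)) {
    signs <- as.integer(intToBits(m - 1L))[seq_len(n)]
    vs[m] <- sum(rk[signs == 1L])
  }
  p_low <- mean(vs <= v_obs)
  p_high <- mean(vs >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

oracle_nearest_centroid <- function(coords, centroids) {
  out_lab <- character(nrow(coords))
  out_d <- numeric(nrow(coords))
  labs <- sort(rownames(centroids))
  for (i in seq_len(nrow(coords))) {
    d <- sapply(labs, function(l) sqrt(sum((coords[i, ] - centroids[l, ])^2)))
    out_lab[i] <- labs[which.min(d)]
    out_d[i] <- min(d)
  }
  list(cohort = out_lab, distance = out_d)
}

# linear scan for the smallest n meeting target noncentral-F power
oracle_power_n <- function(f, alpha, power, k, ncp = "error") {
  n <- k + 1L
  repeat {
    df2 <- n - k
    lambda <- f^2 * if (ncp == "error") df2 else n
    pw <- stats::pf(stats::qf(1 - alpha, k - 1, df2), k - 1, df2,
                    ncp = lambda, lower.tail = FALSE)
    if (pw >= power) return(n)
    n <- n + 1L
    if (n > 1e6) stop("oracle scan exceeded 1e6")
  }
}
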