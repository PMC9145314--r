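# Independent oracles used across the suite. These re-derive quantities by
# brute force (grid refits, plain loops, naive agglomeration) and never call
# the package's optimized code paths.

# Brute-force profile-likelihood bounds: refit the model on a fixed grid of
# candidate BMD values (the potency parameter implied by each), take the
# maximized log-likelihood at each grid point, and read off where the
# profile crosses the chi-square threshold by linear interpolation.
# Supports the members used in the fixtures: E2, E3, E4, H2.
oracle_profile_bounds <- function(data, family, level, bmr, direction,
                                  fit_ll, bmd_hat, conf = 0.90,
                                  n_grid = 200, span = 20) {
  x <- data$dose
  logy <- log(data$response)
  n <- length(logy)
  t <- if (direction == "increasing") 1 + bmr else 1 - bmr
  tag <- paste0(substr(family, 1, 1), level)

  mean_at <- function(bmd, a, cc, d) {
    if (tag == "e2") {
      b <- log(t) / bmd
      a * exp(b * x)
    } else if (tag == "e3") {
      b <- log(t) / bmd^d
      a * exp(b * x^d)
    } else if (tag == "e4") {
      u <- (cc - t) / (cc - 1)
      if (!is.finite(u) || u <= 0) return(rep(NA_real_, length(x)))
      b <- -log(u) / bmd
      a * (cc - (cc - 1) * exp(-b * x))
    } else if (tag == "h2") {
      b <- bmd * t / (1 - t)
      a * (1 - x / (b + x))
    } else stop("oracle does not support ", tag)
  }

  ll_of <- function(mu) {
    if (any(!is.finite(mu)) || any(mu <= 0)) return(-Inf)
    rss <- sum((logy - log(mu))^2)
    -n / 2 * (log(2 * pi * max(rss / n, 1e-12)) + 1)
  }

  a0 <- exp(mean(logy[x == 0]))
  profile_at <- function(bmd) {
    if (tag %in% c("e2", "h2")) {
      o <- stats::optimize(function(la) -ll_of(mean_at(bmd, exp(la))),
                           lower = log(a0) - 3, upper = log(a0) + 3,
                           tol = 1e-9)
      return(-o$objective)
    }
    if (tag == "e3") {
      f <- function(p) {
        v <- ll_of(mean_at(bmd, exp(p[1]), d = min(max(p[2], 1), 4)))
        if (is.finite(v)) -v else 1e10
      }
      starts <- list(c(log(a0), 1.5), c(log(a0), 1), c(log(a0), 3))
    } else {  # e4
      f <- function(p) {
        v <- ll_of(mean_at(bmd, exp(p[1]), cc = exp(p[2])))
        if (is.finite(v)) -v else 1e10
      }
      starts <- list(c(log(a0), log(0.2)), c(log(a0), log(0.5)),
                     c(log(a0), log(0.05)))
    }
    best <- Inf
    for (p0 in starts) {
      r <- tryCatch(stats::optim(p0, f, method = "Nelder-Mead",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(r) && r$value < best) best <- r$value
    }
    -best
  }

  grid <- exp(seq(log(bmd_hat / span), log(bmd_hat * span),
                  length.out = n_grid))
  pl <- vapply(grid, profile_at, 0)
  thr <- fit_ll - stats::qchisq(conf, 1) / 2
  inside <- which(pl >= thr)
  if (!length(inside)) stop("oracle grid never enters the confidence region")
  cross <- function(i_out, i_in) {
    # linear interpolation of the crossing in (log bmd, profile) space
    w <- (thr - pl[i_out]) / (pl[i_in] - pl[i_out])
    exp(log(grid[i_out]) + w * (log(grid[i_in]) - log(grid[i_out])))
  }
  lo_i <- min(inside)
  hi_i <- max(inside)
  bmdl <- if (lo_i == 1) grid[1] else cross(lo_i - 1, lo_i)
  bmdu <- if (hi_i == n_grid) grid[n_grid] else cross(hi_i + 1, hi_i)
  c(bmdl = bmdl, bmdu = bmdu)
}

# Plain-loop weighted running-sum enrichment score (the definition, O(N)).
oracle_es <- function(metric, hits, p = 1) {
  N <- length(metric)
  nh <- sum(hits)
  if (nh == 0 || nh == N) return(0)
  w <- abs(metric)^p
  sw <- sum(w[hits])
  if (sw == 0) { w <- rep(1, N); sw <- nh }
  rs <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (hits[i]) w[i] / sw else -1 / (N - nh)
    if (rs > best_pos) best_pos <- rs
    if (rs < best_neg) best_neg <- rs
  }
  if (best_pos >= -best_neg - 1e-12) best_pos else best_neg
}

# Naive average-linkage agglomeration over a distance matrix; returns merge
# heights (sorted) and the flat partition at k clusters.
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# Membership signature of a partition (list of index vectors) for comparison
# irrespective of cluster order.
partition_signature <- function(clusters, n) {
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  # canonicalize: relabel by first occurrence
  match(lab, unique(lab))
}

# hclust partition at k clusters as a signature.
hclust_signature <- function(hc, k, n) {
  as.integer(match(stats::cutree(hc, k = k), unique(stats::cutree(hc, k = k))))
}
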