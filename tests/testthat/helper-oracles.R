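# Independent brute-force oracles. These deliberately share no code with the
# package internals: point-in-polygon is re-implemented in R, the K function
# is a plain double loop, and isotropic weights come from discretising the
# circle rather than exact arc intersection.

oracle_pip <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    cnt <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > py[k]) != (yj > py[k])) {
        xint <- xj + (py[k] - yj) / (yi - yj) * (xi - xj)
        if (px[k] < xint) cnt <- !cnt
      }
      j <- i
    }
    inside[k] <- cnt
  }
  inside
}

# K with no correction: plain double loop over ordered pairs
oracle_k_none <- function(x, y, area, sgrid) {
  n <- length(x)
  sapply(sgrid, function(s) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= s) cnt <- cnt + 1
    }
    area / n^2 * cnt
  })
}

# isotropic weight by circle discretisation (independent of the exact
# arc-intersection code path)
oracle_iso_weight <- function(cx, cy, r, poly, m = 8192) {
  th <- (seq_len(m) - 0.5) / m * 2 * pi
  frac <- mean(oracle_pip(cx + r * cos(th), cy + r * sin(th), poly))
  1 / max(frac, 1e-6)
}

oracle_k_iso <- function(x, y, area, poly, sgrid) {
  n <- length(x)
  vals <- numeric(length(sgrid))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    hit <- sgrid >= d
    if (any(hit)) {
      w <- if (d > 0) oracle_iso_weight(x[i], y[i], d, poly) else 1
      vals[hit] <- vals[hit] + w
    }
  }
  area / n^2 * vals
}

oracle_d_none <- function(x, y, is_case, area, sgrid) {
  oracle_k_none(x[is_case], y[is_case], area, sgrid) -
    oracle_k_none(x[!is_case], y[!is_case], area, sgrid)
}

# all distinct scan windows by brute force over a dense radius grid
oracle_windows <- function(x, y, is_case, max_radius) {
  out <- list()
  for (c0 in which(is_case)) {
    d <- sqrt((x - x[c0])^2 + (y - y[c0])^2)
    cand <- sort(unique(d))
    grid <- unique(pmin(c(0, cand, cand + 1e-9, (cand[-1] + cand[-length(cand)]) / 2,
                          max_radius), max_radius))
    sets <- unique(lapply(grid[grid <= max_radius],
                          function(r) sort(which(d <= r))))
    out[[as.character(c0)]] <- sets
  }
  out
}

# the likelihood kernel written straight from its count definition
oracle_llr <- function(n_in, N_in, n_out, M_out) {
  if (M_out <= 0 || n_in * M_out <= n_out * N_in) return(-Inf)
  (if (n_in > 0) n_in * log(n_in / N_in) else 0) +
    (if (n_out > 0) n_out * log(n_out / M_out) else 0)
}

# full brute maximum of the likelihood kernel over every (case centre, radius)
oracle_max_llr <- function(x, y, is_case, max_radius) {
  C <- sum(is_case); n <- length(x)
  best <- -Inf
  for (c0 in which(is_case)) {
    d <- sqrt((x - x[c0])^2 + (y - y[c0])^2)
    for (r in sort(unique(d[d <= max_radius]))) {
      inside <- d <= r
      n_in <- sum(is_case[inside]); N_in <- sum(inside)
      llr <- oracle_llr(n_in, N_in, C - n_in, n - N_in)
      if (llr > best) best <- llr
    }
  }
  best
}

random_cc_instance <- function(n_max = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample(8:n_max, 1)
  side <- runif(1, 1000, 10000)
  w <- rect_window(0, side, 0, side)
  x <- runif(n, 0, side); y <- runif(n, 0, side)
  nc <- sample(2:(n - 2), 1)
  lab <- sample(rep(c("case", "control"), c(nc, n - nc)))
  list(window = w, x = x, y = y, label = lab,
       data = cc_pattern(x, y, lab, w))
}
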