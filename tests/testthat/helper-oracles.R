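# Independent oracles, deliberately written as brute force and kept apart
# from the package's own code paths.

# exhaustive between-class-variance scan: for every candidate cut between
# two consecutive bins, compute the variance of class means directly from
# the definition and return the lowest maximizing threshold
oracle_bcv_threshold <- function(gray, n_bins = 256L, range = NULL) {
  v <- as.numeric(gray)
  if (is.null(range)) range <- c(min(v), max(v))
  bw <- (range[2] - range[1]) / n_bins
  idx <- pmin(pmax(floor((v - range[1]) / bw), 0), n_bins - 1) + 1
  mids <- range[1] + (seq_len(n_bins) - 0.5) * bw
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(n_bins - 1)) {
    bg <- idx <= k
    n0 <- sum(bg); n1 <- sum(!bg)
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(mids[idx[bg]]) - mean(mids[idx[!bg]]))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_k <- k
    }
  }
  range[1] + best_k * bw
}

# between-class variance of a particular cut, from the definition
oracle_bcv_value <- function(gray, threshold, n_bins = 256L, range = NULL) {
  v <- as.numeric(gray)
  if (is.null(range)) range <- c(min(v), max(v))
  bw <- (range[2] - range[1]) / n_bins
  idx <- pmin(pmax(floor((v - range[1]) / bw), 0), n_bins - 1) + 1
  mids <- range[1] + (seq_len(n_bins) - 0.5) * bw
  k <- round((threshold - range[1]) / bw)
  bg <- idx <= k
  if (!any(bg) || all(bg)) return(-Inf)
  w0 <- mean(bg)
  w0 * (1 - w0) * (mean(mids[idx[bg]]) - mean(mids[idx[!bg]]))^2
}

# mid-ranks computed explicitly by sorting and tie averaging, then plain
# Pearson from its definition
oracle_midrank_pearson <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small deterministic cell-record table
make_records <- function(n, seed = 1) {
  set.seed(seed)
  px <- sample(50:400, n, replace = TRUE)
  chl <- stats::runif(n, 1e3, 1e5)
  lip <- stats::runif(n, 10, 1e4)
  data.frame(field_id = "f1", cell_id = seq_len(n), pixel_count = px,
             equiv_diameter = 2 * sqrt(px / pi),
             chl_amount = chl,
             lipid_amount = lip,
             chl_density = chl / px,
             lipid_density = lip / px,
             saturated_fraction_chl = 0, saturated_fraction_lipid = 0,
             timepoint = 0, condition = "control",
             stringsAsFactors = FALSE)
}
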