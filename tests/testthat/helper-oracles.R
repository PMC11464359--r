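# Independent reference implementations used as oracles. They deliberately
# recompute everything from raw inputs with plain loops instead of sharing
# code with the package.

# Otsu: direct per-threshold evaluation of the class proportions, class
# means and inter-class variance from a 256-bin histogram of counts.
otsu_oracle <- function(counts) {
  lv <- 0:255
  N <- sum(counts)
  mu <- sum(lv * counts) / N
  S <- numeric(256)
  for (t in 0:255) {
    n0 <- sum(counts[seq_len(t + 1)])
    n1 <- N - n0
    w0 <- n0 / N
    w1 <- n1 / N
    mu0 <- if (n0 > 0) sum(lv[seq_len(t + 1)] * counts[seq_len(t + 1)]) / n0 else 0
    mu1 <- if (n1 > 0) sum(lv[(t + 2):256] * counts[(t + 2):256]) / n1 else 0
    S[t + 1] <- w0 * (mu0 - mu)^2 + w1 * (mu1 - mu)^2
  }
  list(T = which.max(S) - 1L, S = max(S), curve = S)
}

# Scalar per-pixel reference for the color indices (no vectorization).
index_oracle_pixel <- function(R, G, B, name) {
  s <- R + G + B
  if (s == 0) return(0)
  r <- R / s; g <- G / s; b <- B / s
  switch(name,
    EXG = 2 * g - r - b,
    Cg = 0.4 * g - 0.3 * r - 0.1 * b,
    EXG_EXR = 3 * g - 2.4 * r - b,
    EXR = 1.4 * r - g,
    GBDI = g - b,
    NGBDI = if (g + b == 0) 0 else (g - b) / (g + b),
    NGRDI = if (g + r == 0) 0 else (g - r) / (g + r),
    S = if (max(R, G, B) > 0) 1 - min(R, G, B) / max(R, G, B) else 0
  )
}

# Brute-force average precision: enumerate every confidence cutoff, build
# the precision-recall points with a fresh greedy matcher, and integrate
# the stepwise precision envelope directly.
iou_one <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

greedy_tp_flags <- function(preds, gts, thr) {
  ord <- order(-preds$confidence)
  taken <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(preds))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- 0; bestj <- 0
    for (j in seq_len(nrow(gts))) {
      if (taken[j]) next
      v <- iou_one(as.numeric(preds[i, c("x_min", "y_min", "x_max", "y_max")]),
                   as.numeric(gts[j, c("x_min", "y_min", "x_max", "y_max")]))
      if (v >= thr && v > best) { best <- v; bestj <- j }
    }
    if (bestj > 0) { taken[bestj] <- TRUE; tp[k] <- TRUE }
  }
  tp # in descending-confidence order
}

ap_oracle <- function(preds, gts, thr = 0.5) {
  n_gt <- nrow(gts)
  if (n_gt == 0 || nrow(preds) == 0) return(0)
  tp <- greedy_tp_flags(preds, gts, thr)
  cuts <- seq_along(tp) # every cutoff: top-k predictions kept
  pr <- t(vapply(cuts, function(k) {
    c(R = sum(tp[1:k]) / n_gt, P = sum(tp[1:k]) / k)
  }, numeric(2)))
  # stepwise envelope over recall
  env <- pr[, "P"]
  for (i in rev(seq_len(length(env) - 1))) env[i] <- max(env[i], env[i + 1])
  rec <- c(0, pr[, "R"])
  sum((rec[-1] - rec[-length(rec)]) * env)
}

# Random detection instance for the AP oracle tests.
random_instance <- function(n_pred, n_gt, size = 100) {
  mk <- function(n) {
    x <- runif(n, 0, size - 12); y <- runif(n, 0, size - 12)
    w <- runif(n, 4, 12); h <- runif(n, 4, 12)
    data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
  }
  gts <- mk(n_gt)
  # predictions: jittered copies of some gts plus spurious boxes
  n_match <- if (n_pred > 0 && n_gt > 0) sample(0:min(n_pred, n_gt), 1) else 0
  preds <- mk(n_pred)
  if (n_match > 0) {
    pick <- sample(seq_len(n_gt), n_match)
    jit <- matrix(runif(4 * n_match, -3, 3), ncol = 4)
    preds[seq_len(n_match), ] <- gts[pick, ] + jit
    preds$x_max <- pmax(preds$x_max, preds$x_min + 1)
    preds$y_max <- pmax(preds$y_max, preds$y_min + 1)
  }
  preds$confidence <- round(runif(n_pred), 3)
  list(preds = preds, gts = gts)
}
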