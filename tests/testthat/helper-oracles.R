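# Independent oracles used to cross-check the package's metric and
# clustering implementations. Deliberately written brute-force (explicit
# loops, exhaustive enumeration) so they share no code path with the
# vectorized implementations they check.

# per-pixel counting oracle for Dice / ME / precision / recall
oracle_pixel_metrics <- function(truth, pred) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L; signed <- 0
  for (i in seq_along(truth)) {
    a <- truth[i] != 0; b <- pred[i] != 0
    if (a && b) tp <- tp + 1L
    else if (!a && b) fp <- fp + 1L
    else if (a && !b) fn <- fn + 1L
    else tn <- tn + 1L
    signed <- signed + (as.integer(b) - as.integer(a))
  }
  list(
    dice = if (2L * tp + fp + fn == 0L) 1 else 2 * tp / (2L * tp + fp + fn),
    me = signed / length(truth),
    precision = if (tp + fp > 0L) tp / (tp + fp) else 1,
    recall = if (tp + fn > 0L) tp / (tp + fn) else 1)
}

# exhaustive assignment oracle: over all one-to-one matchings restricted to
# pairs with dice > threshold, maximize matched count, then total dice
oracle_match <- function(dmat, threshold) {
  np <- nrow(dmat); nt <- ncol(dmat)
  best <- list(count = -1L, total = -Inf, pairs = NULL)
  rec <- function(p, used_t, pairs, total) {
    if (p > np) {
      cnt <- nrow(pairs)
      if (cnt > best$count || (cnt == best$count && total > best$total)) {
        best <<- list(count = cnt, total = total, pairs = pairs)
      }
      return(invisible())
    }
    rec(p + 1L, used_t, pairs, total)  # leave pred p unmatched
    for (t in seq_len(nt)) {
      if (!used_t[t] && dmat[p, t] > threshold) {
        rec(p + 1L, replace(used_t, t, TRUE),
            rbind(pairs, c(p, t)), total + dmat[p, t])
      }
    }
  }
  rec(1L, rep(FALSE, nt), matrix(integer(), 0, 2), 0)
  best
}

# brute-force PR staircase integral: for each recall level, the envelope
# precision is the max precision at recall >= r; O(n^2) loops
oracle_ap <- function(tp_flags, n_truth) {
  n <- length(tp_flags)
  if (n_truth == 0L) return(0)
  prec <- numeric(n); rec <- numeric(n)
  ctp <- 0L
  for (i in seq_len(n)) {
    ctp <- ctp + as.integer(tp_flags[i])
    prec[i] <- ctp / i
    rec[i] <- ctp / n_truth
  }
  ap <- 0
  prev_r <- 0
  for (i in seq_len(n)) {
    pmax_i <- 0
    for (j in seq_len(n)) if (rec[j] >= rec[i]) pmax_i <- max(pmax_i, prec[j])
    ap <- ap + (rec[i] - prev_r) * pmax_i
    prev_r <- rec[i]
  }
  ap
}

# transitive closure of "within eps" over a pixel set, via single-linkage
# hierarchical clustering cut at eps
oracle_transitive_clusters <- function(coords, eps) {
  if (nrow(coords) == 1L) return(1L)
  hc <- stats::hclust(stats::dist(coords), method = "single")
  stats::cutree(hc, h = eps)
}

# normal-equations least squares of x on y
oracle_slope_angle <- function(x, y) {
  X <- cbind(1, y)
  beta <- solve(t(X) %*% X, t(X) %*% x)
  atan(beta[2]) * 180 / pi
}

# numerical-integration oracle for the two-sided t-test p value
oracle_t_pvalue <- function(t, df) {
  upper <- stats::integrate(function(u) stats::dt(u, df), abs(t), Inf,
                            rel.tol = 1e-12)$value
  2 * upper
}

# random disjoint rectangular instances plus perturbed predictions: the
# layout of a realistic detector output (mostly one pred per truth, some
# dropped, some spurious)
random_instance_case <- function(h = 48, w = 48, max_k = 6) {
  k <- sample.int(max_k, 1)
  truths <- matrix(0L, h, w)
  slots <- floor(w / max_k)
  for (t in seq_len(k)) {
    x0 <- (t - 1) * slots + sample.int(2, 1)
    x1 <- min(w, x0 + sample(3:(slots - 1), 1))
    y0 <- sample.int(h - 12, 1); y1 <- min(h, y0 + sample(6:12, 1))
    truths[y0:y1, x0:x1] <- t
  }
  preds <- matrix(0L, h, w)
  p <- 0L
  for (t in seq_len(k)) {
    if (runif(1) < 0.15) next  # dropped detection
    p <- p + 1L
    dy <- sample(-3:3, 1); dx <- sample(-3:3, 1)
    m <- truths == t
    idx <- which(m, arr.ind = TRUE)
    r <- pmin(pmax(idx[, 1] + dy, 1), h); c <- pmin(pmax(idx[, 2] + dx, 1), w)
    preds[cbind(r, c)] <- p
  }
  if (runif(1) < 0.4) {  # spurious detection
    p <- p + 1L
    y0 <- sample.int(h - 4, 1); x0 <- sample.int(w - 4, 1)
    preds[y0:(y0 + 3), x0:(x0 + 3)] <- p
  }
  list(preds = preds, truths = truths)
}

# pairwise dice matrix computed by explicit set counting
oracle_dice_matrix <- function(preds, truths) {
  pid <- sort(setdiff(unique(as.vector(preds)), 0L))
  tid <- sort(setdiff(unique(as.vector(truths)), 0L))
  d <- matrix(0, length(pid), length(tid))
  for (i in seq_along(pid)) for (j in seq_along(tid)) {
    a <- preds == pid[i]; b <- truths == tid[j]
    d[i, j] <- 2 * sum(a & b) / (sum(a) + sum(b))
  }
  list(d = d, pid = pid, tid = tid)
}
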