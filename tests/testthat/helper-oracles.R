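# Independent reference implementations used to cross-check the package's
# code paths. Each deliberately takes a different route than the package:
# t.test vs closed form, explicit step-up vs p.adjust, choose() enumeration
# vs phyper, Lance-Williams agglomeration vs hclust.

welch_ref <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

bh_ref <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

hyper_tail_ref <- function(k, set_size, universe, query) {
  xs <- k:min(set_size, query)
  sum(choose(set_size, xs) * choose(universe - set_size, query - xs)) /
    choose(universe, query)
}

# Ward-D2 by the Lance-Williams recurrence on squared Euclidean distances;
# heights are the square roots of the merge criteria.
ward_ref <- function(mat) {
  n <- nrow(mat)
  D2 <- as.matrix(stats::dist(mat))^2
  size <- rep(1, n)
  active <- seq_len(n)
  id <- -seq_len(n)
  heights <- numeric(n - 1)
  merge <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- 0L
    for (a in seq_along(active)) for (b in seq_along(active)) if (a < b) {
      i <- active[a]; j <- active[b]
      if (D2[i, j] < best) { best <- D2[i, j]; bi <- i; bj <- j }
    }
    heights[k] <- sqrt(best)
    merge[k, ] <- sort(c(id[bi], id[bj]))
    for (x in active) if (x != bi && x != bj) {
      ni <- size[bi]; nj <- size[bj]; nk <- size[x]
      D2[bi, x] <- D2[x, bi] <-
        ((ni + nk) * D2[bi, x] + (nj + nk) * D2[bj, x] - nk * best) /
        (ni + nj + nk)
    }
    size[bi] <- size[bi] + size[bj]
    id[bi] <- k
    active <- setdiff(active, bj)
  }
  list(merge = merge, height = heights)
}

# member-set keys from a merge matrix in hclust convention
merge_member_sets <- function(merge, labels) {
  n <- length(labels)
  idx <- vector("list", n - 1)
  keys <- character(n - 1)
  for (k in seq_len(n - 1)) {
    members <- integer()
    for (child in merge[k, ])
      members <- c(members, if (child < 0) -child else idx[[child]])
    idx[[k]] <- members
    keys[k] <- paste(sort(labels[members]), collapse = "\t")
  }
  keys
}

# naive per-protein presence enumeration (6-of-9 rule)
presence_ref <- function(qt, presence_min) {
  keep <- logical(nrow(qt$values))
  for (i in seq_len(nrow(qt$values))) {
    ok <- TRUE
    for (cc in unique(qt$columns$condition)) {
      cols <- which(qt$columns$condition == cc)
      cnt <- 0L
      for (j in cols) if (!is.na(qt$values[i, j])) cnt <- cnt + 1L
      if (cnt < presence_min) ok <- FALSE
    }
    keep[i] <- ok
  }
  qt$protein_id[keep]
}
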