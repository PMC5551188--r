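# Brute-force reference implementations used as independent oracles.

# Reference bagged forest: mirrors the engine's documented RNG draw order
# (bootstrap draws, then per-node partial Fisher-Yates mtry selection,
# depth-first growth) but finds each node's best split by naive
# enumeration: every candidate threshold is evaluated by explicitly
# partitioning the node sample and summing squared deviations from the
# child means.
# sequential double-precision accumulation (R's mean()/sum() use extended
# precision; the engine specifies plain double adds)
seq_sum <- function(v) { s <- 0; for (x in v) s <- s + x; s }
seq_mean <- function(v) seq_sum(v) / length(v)

oracle_forest <- function(X, y, ntree, mtry, min_split = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  grow <- function(rows) {
    node <- list(var = NA, split = NA, left = NULL, right = NULL,
                 value = seq_mean(y[rows]))
    if (length(rows) < min_split || length(unique(y[rows])) == 1) return(node)
    cand <- integer(mtry)
    pool <- seq_len(p)
    for (k in seq_len(mtry)) {
      j <- k + floor(runif(1) * (p - k + 1))
      if (j > p) j <- p
      tmp <- pool[k]; pool[k] <- pool[j]; pool[j] <- tmp
      cand[k] <- pool[k]
    }
    best <- list(crit = Inf, var = NA, split = NA)
    nn <- length(rows)
    for (v in cand) {
      # canonical node-sample order: by value, then by row index
      o <- rows[order(X[rows, v], rows)]
      xv <- X[o, v]
      if (xv[1] == xv[nn]) next
      # node totals via sequential double accumulation
      tot <- 0; tot2 <- 0
      for (i in seq_len(nn)) { tot <- tot + y[o[i]]; tot2 <- tot2 + y[o[i]]^2 }
      for (i in seq_len(nn - 1)) {
        if (xv[i] == xv[i + 1]) next
        # left sums by sequential adds, right sums by sequential
        # subtraction from the totals (the documented criterion arithmetic)
        sl <- 0; ssl <- 0; sr <- tot; ssr <- tot2
        for (k in seq_len(i)) {
          sl <- sl + y[o[k]]; ssl <- ssl + y[o[k]]^2
          sr <- sr - y[o[k]]; ssr <- ssr - y[o[k]]^2
        }
        nl <- i; nr <- nn - i
        crit <- (ssl - sl * sl / nl) + (ssr - sr * sr / nr)
        mid <- (xv[i] + xv[i + 1]) / 2
        if (!(mid < xv[i + 1])) mid <- xv[i]
        if (crit < best$crit) best <- list(crit = crit, var = v, split = mid)
      }
    }
    if (is.na(best$var)) return(node)
    node$var <- best$var; node$split <- best$split
    l <- rows[X[rows, best$var] <= best$split]
    r <- rows[X[rows, best$var] > best$split]
    node$left <- grow(l)
    node$right <- grow(r)
    node
  }

  trees <- vector("list", ntree)
  inbag <- matrix(0L, n, ntree)
  for (t in seq_len(ntree)) {
    idx <- floor(runif(n) * n) + 1
    idx[idx > n] <- n
    for (i in idx) inbag[i, t] <- inbag[i, t] + 1L
    trees[[t]] <- grow(idx)
  }
  list(trees = trees, inbag = inbag, y = y)
}

oracle_predict_tree <- function(node, xrow) {
  while (!is.na(node$var)) {
    node <- if (xrow[node$var] <= node$split) node$left else node$right
  }
  node$value
}

oracle_oob_predict <- function(fit, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    preds <- c()
    for (t in seq_along(fit$trees)) {
      if (fit$inbag[i, t] == 0)
        preds <- c(preds, oracle_predict_tree(fit$trees[[t]], X[i, ]))
    }
    if (length(preds)) out[i] <- seq_mean(preds)
  }
  out
}
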