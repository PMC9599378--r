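# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: pair counting instead of contingency
# tables, explicit loops instead of vectorized marginals.

# adjusted Rand index by enumerating all C(n,2) cell pairs
brute_ari <- function(x, y) {
  n <- length(x)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]
    sy <- y[i] == y[j]
    if (sx && sy) n11 <- n11 + 1
    else if (sx) n10 <- n10 + 1
    else if (sy) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

random_partition <- function(n, kmax = 5) {
  sample.int(sample(2:kmax, 1), n, replace = TRUE)
}

# per-row variance of off-diagonal ARI entries, computed longhand
brute_row_variances <- function(partitions) {
  k <- length(partitions)
  R <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    li <- clusterLabels(partitions[[i]])
    lj <- clusterLabels(partitions[[j]])[names(clusterLabels(partitions[[i]]))]
    R[i, j] <- brute_ari(unname(li), unname(lj))
  }
  vapply(seq_len(k), function(i) {
    v <- R[i, setdiff(seq_len(k), i)]
    sum((v - mean(v))^2) / (length(v) - 1)
  }, 1.0)
}

# exhaustive unanimous co-clustering relation over all cell pairs
brute_consensus_pairs <- function(partitions) {
  cells <- names(clusterLabels(partitions[[1]]))
  n <- length(cells)
  out <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- vapply(partitions, function(p) {
      l <- clusterLabels(p)
      l[[cells[i]]] == l[[cells[j]]]
    }, TRUE)
    if (all(same))
      out <- c(out, paste(sort(c(cells[i], cells[j])), collapse = "|"))
  }
  sort(out)
}

graph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character())
  sort(apply(el, 1, function(e) paste(sort(e), collapse = "|")))
}

# evaluation metrics computed longhand from per-type counts
brute_metrics <- function(cm) {
  T_ <- nrow(cm)
  n <- sum(cm)
  tp <- fp <- fn <- row_t <- col_t <- numeric(T_)
  for (t in seq_len(T_)) {
    tp[t] <- cm[t, t]
    row_t[t] <- sum(cm[t, ])
    col_t[t] <- sum(cm[, t])
    fn[t] <- row_t[t] - tp[t]
    fp[t] <- col_t[t] - tp[t]
  }
  recall <- numeric(T_); precision <- numeric(T_)
  for (t in seq_len(T_)) {
    recall[t] <- if (tp[t] + fn[t] > 0) tp[t] / (tp[t] + fn[t]) else 0
    precision[t] <- if (tp[t] + fp[t] > 0) tp[t] / (tp[t] + fp[t]) else 0
  }
  avg_p <- mean(precision); avg_r <- mean(recall)
  f1 <- if (avg_p + avg_r == 0) 0 else 2 * avg_p * avg_r / (avg_p + avg_r)
  num <- sum(tp) * n - sum(col_t * row_t)
  den <- sqrt((n^2 - sum(col_t^2)) * (n^2 - sum(row_t^2)))
  mcc <- if (den == 0) 0 else num / den
  c(accuracy = sum(tp) / n, balanced_accuracy = avg_r, macro_f1 = f1,
    mcc = mcc)
}

random_confusion <- function(tmax = 6, nmax = 500) {
  T_ <- sample(2:tmax, 1)
  n <- sample(T_:nmax, 1)
  cm <- matrix(0L, T_, T_)
  ix <- cbind(sample.int(T_, n, replace = TRUE),
              sample.int(T_, n, replace = TRUE))
  for (r in seq_len(n)) cm[ix[r, 1], ix[r, 2]] <- cm[ix[r, 1], ix[r, 2]] + 1L
  dimnames(cm) <- list(paste0("t", seq_len(T_)), paste0("t", seq_len(T_)))
  cm
}

run_quiet <- function(...) {
  suppressMessages(suppressWarnings(runACAM(...)))
}

# nearest labelled neighbour by exhaustive distance scan
brute_nn1 <- function(emb, labeled, unlabeled) {
  L <- emb[names(labeled), , drop = FALSE]
  out <- character(length(unlabeled))
  for (i in seq_along(unlabeled)) {
    q <- emb[unlabeled[i], ]
    d <- sqrt(rowSums((L - matrix(q, nrow(L), ncol(L), byrow = TRUE))^2))
    out[i] <- labeled[[which.min(d)]]
  }
  stats::setNames(out, unlabeled)
}

# tiny log-scale expression fixture: a SingleCellExperiment with planted
# cluster structure, built directly (no generator) for unit tests
make_log_sce <- function(m) {
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m, logcounts = m))
}
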