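# Brute-force oracles, written as plain loops independent of the package
# internals, used to freeze or cross-check expected values.

# Geometric ABC categorization: returns "A"/"B"/"C" per original index.
oracle_abc <- function(values) {
  n <- length(values)
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  total <- sum(v)
  yields <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + v[i]
    yields[i] <- acc / total
  }
  best_i <- 1L
  best_d <- Inf
  for (i in seq_len(n)) {
    d <- sqrt((i / n)^2 + (1 - yields[i])^2)
    if (d < best_d - 1e-12) {
      best_d <- d
      best_i <- i
    }
  }
  break_even <- n + 1L
  for (i in seq_len(n)) {
    prev <- if (i == 1L) 0 else yields[i - 1L]
    slope <- (yields[i] - prev) * n
    if (slope < 1 - 1e-12) {
      break_even <- i
      break
    }
  }
  bc <- max(best_i, break_even - 1L)
  sets <- rep("C", n)
  sets[seq_len(bc)] <- "B"
  sets[seq_len(best_i)] <- "A"
  out <- character(n)
  out[ord] <- sets
  out
}

abc_sets_by_index <- function(res) {
  out <- character(nrow(res$assignment))
  out[res$assignment$item] <- as.character(res$assignment$set)
  out
}

# kNN imputation oracle for one missing cell of a subjects-by-slots matrix.
oracle_knn_value <- function(m, i, j, k) {
  ds <- rep(NA_real_, nrow(m))
  for (r in seq_len(nrow(m))[-i]) {
    common <- which(!is.na(m[i, ]) & !is.na(m[r, ]))
    if (length(common) == 0 || is.na(m[r, j])) next
    ds[r] <- sqrt(sum((m[i, common] - m[r, common])^2) / length(common))
  }
  cand <- which(!is.na(ds))
  if (length(cand) < k) {
    return(mean(m[, j], na.rm = TRUE))
  }
  nb <- cand[order(ds[cand])][seq_len(k)]
  w <- exp(-ds[nb])
  sum(w * m[nb, j]) / sum(w)
}

# Shortest-path distances from the bond list by breadth-first search.
oracle_graph_distances <- function(n_atoms, bonds) {
  d <- matrix(Inf, n_atoms, n_atoms)
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], bonds$a2[b])
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], bonds$a1[b])
  }
  for (start in seq_len(n_atoms)) {
    d[start, start] <- 0
    frontier <- start
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (a in frontier) {
        for (b in adj[[a]]) {
          if (d[start, b] > depth) {
            d[start, b] <- depth
            nxt <- c(nxt, b)
          }
        }
      }
      frontier <- nxt
    }
  }
  d
}

# Count of typed-atom pairs at one topological distance (same-type pairs).
oracle_same_type_pairs <- function(mol, types_list, type, dist) {
  atoms <- which(vapply(types_list, function(t) type %in% t, logical(1)))
  d <- oracle_graph_distances(nrow(mol$atoms), mol$bonds)
  cnt <- 0L
  if (length(atoms) >= 2) {
    for (i in seq_len(length(atoms) - 1)) {
      for (j in seq(i + 1, length(atoms))) {
        if (d[atoms[i], atoms[j]] == dist) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# Variance/correlation descriptor filter, re-derived step by step.
oracle_filter_columns <- function(m, var_min, cor_max) {
  keep <- colnames(m)[apply(m, 2, stats::var) >= var_min]
  m <- m[, keep, drop = FALSE]
  repeat {
    if (ncol(m) < 2) break
    cm <- abs(stats::cor(m))
    diag(cm) <- 0
    if (max(cm) <= cor_max) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    ma <- colMeans(abs(stats::cor(m)))
    drop_idx <- if (ma[idx[1]] > ma[idx[2]]) idx[1] else
      if (ma[idx[1]] < ma[idx[2]]) idx[2] else max(idx)
    m <- m[, -drop_idx, drop = FALSE]
  }
  colnames(m)
}
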