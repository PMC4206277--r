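# independent brute-force oracles, deliberately written from the bare
# definitions (BFS path counting, Faddeev-LeVerrier characteristic
# polynomial, literal TP/FP recounts) so they share no code with the
# implementation they check

# adjacency matrix of a contact_graph
oracle_adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n)
  if (nrow(g$edges)) {
    e <- cbind(match(g$edges[, 1], g$nodes), match(g$edges[, 2], g$nodes))
    A[e] <- 1
    A[e[, 2:1, drop = FALSE]] <- 1
  }
  A
}

# BFS distances and shortest-path counts from one source
oracle_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  sigma <- rep(0, n)
  d[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(A[v, ] > 0)) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
        if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sigma)
}

# the ten topology descriptors, recomputed from first principles
oracle_topology <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  deg <- rowSums(A)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(A, s))
  D <- do.call(rbind, lapply(bfs, `[[`, "d"))

  # connected components from reachability
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(D[v, ])] <- cid
    }
  }
  degc <- clo <- btw <- numeric(n)
  for (c in unique(comp)) {
    members <- which(comp == c)
    nc <- length(members)
    if (nc == 1) next
    degc[members] <- deg[members] / (nc - 1)
    clo[members] <- (nc - 1) / rowSums(D[members, members, drop = FALSE])
    if (nc >= 3) {
      for (v in members) {
        tot <- 0
        others <- setdiff(members, v)
        for (si in seq_along(others)) {
          s <- others[si]
          for (t in others[-seq_len(si)]) {
            if (!is.finite(D[s, t])) next
            sig_st <- bfs[[s]]$sigma[t]
            if (D[s, v] + D[v, t] == D[s, t] && sig_st > 0) {
              tot <- tot + bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] / sig_st
            }
          }
        }
        btw[v] <- tot / ((nc - 1) * (nc - 2) / 2)
      }
    }
  }
  sizes <- table(comp)
  big <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(comp == big)
  if (length(members) == 1) {
    rad <- diam <- aecc <- 0
  } else {
    ecc <- apply(D[members, members, drop = FALSE], 1, max)
    rad <- min(ecc); diam <- max(ecc); aecc <- mean(ecc)
  }
  # local clustering: fraction of closed neighbour pairs
  clust <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
  c(n, sum(A) / 2, mean(degc), mean(clo), mean(btw), rad, diam, aecc,
    sum(deg == 1), mean(clust))
}

# eigenvalues via the Faddeev-LeVerrier characteristic polynomial + polyroot
oracle_eigenvalues <- function(A) {
  n <- nrow(A)
  cvec <- numeric(n)
  M <- diag(n)
  for (k in seq_len(n)) {
    if (k > 1) M <- A %*% M + cvec[k - 1] * diag(n)
    cvec[k] <- -sum(diag(A %*% M)) / k
  }
  # p(lambda) = lambda^n + c1 lambda^(n-1) + ... + cn; polyroot wants
  # ascending coefficients
  r <- polyroot(rev(c(1, cvec)))
  sort(Re(r), decreasing = TRUE)
}

# dominant eigenvalue by shifted power iteration (independent of eigen())
oracle_lambda1 <- function(A, iters = 500) {
  n <- nrow(A)
  B <- A + n * diag(n)     # shift to make the dominant eigenvalue unique+
  v <- rep(1 / sqrt(n), n)
  for (k in seq_len(iters)) {
    w <- B %*% v
    v <- as.numeric(w) / sqrt(sum(w^2))
  }
  as.numeric(t(v) %*% A %*% v)
}

# power sums tr(A^k) = sum_i lambda_i^k, computed by plain multiplication
oracle_power_sums <- function(A, kmax) {
  M <- diag(nrow(A))
  vapply(seq_len(kmax), function(k) {
    M <<- M %*% A
    sum(diag(M))
  }, numeric(1))
}

# literal accuracy/coverage recount
oracle_acc_cov <- function(ranked, native_pairs, L, divisor, lo, hi = Inf) {
  sep <- ranked$j - ranked$i
  keep <- sep >= lo & sep <= hi
  preds <- ranked[keep, , drop = FALSE]
  n_top <- max(1, floor(L / divisor))
  n_eval <- min(n_top, nrow(preds))
  nat <- paste(native_pairs[, 1], native_pairs[, 2])
  nsep <- native_pairs[, 2] - native_pairs[, 1]
  tp_total <- sum(nsep >= lo & nsep <= hi)
  if (n_eval == 0) return(list(acc = NA_real_, tp = 0, fp = 0,
                               tp_total = tp_total))
  tp <- 0
  for (r in seq_len(n_eval)) {
    if (paste(preds$i[r], preds$j[r]) %in% nat) tp <- tp + 1
  }
  list(acc = tp / n_eval, tp = tp, fp = n_eval - tp, tp_total = tp_total,
       cov = if (tp_total > 0) tp / tp_total else NA_real_)
}

# seeded random graph on 1..n with edge probability p
random_test_graph <- function(n, p) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  structure(list(nodes = seq_len(n),
                 edges = matrix(as.integer(edges), ncol = 2),
                 anchor = NULL),
            class = "contact_graph")
}
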