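# Independent brute-force oracles. These deliberately avoid the package's
# internal helpers (separate entropy code, direct path enumeration, explicit
# combinatorial sums) so they can certify the implementation.

# --- information theory -----------------------------------------------------

oracle_mi <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  mi <- 0
  for (a in ux) for (b in uy) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  mi
}

# two-level map equation evaluated literally: q*H(Q) + sum_m p_m*H(P_m)
oracle_map_equation <- function(adj, memb) {
  k <- rowSums(adj)
  tw <- sum(k)
  mods <- sort(unique(memb))
  q <- numeric(length(mods))
  for (mi in seq_along(mods)) {
    inm <- memb == mods[mi]
    q[mi] <- sum(adj[inm, !inm, drop = FALSE]) / tw
  }
  qt <- sum(q)
  ent <- function(p) {
    p <- p[p > 0] / sum(p)
    -sum(p * log2(p))
  }
  L <- if (qt > 0) qt * ent(q) else 0
  for (mi in seq_along(mods)) {
    inm <- memb == mods[mi]
    rates <- c(q[mi], k[inm] / tw)
    pm <- sum(rates)
    if (pm > 0) L <- L + pm * ent(rates)
  }
  L
}

oracle_modularity <- function(adj, memb) {
  m <- sum(adj) / 2
  mods <- unique(memb)
  qq <- 0
  for (mm in mods) {
    inm <- memb == mm
    e_c <- sum(adj[inm, inm, drop = FALSE]) / 2
    d_c <- sum(adj[inm, , drop = FALSE])
    qq <- qq + e_c / m - (d_c / (2 * m))^2
  }
  qq
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  ha <- 0; hb <- 0; iab <- 0
  for (x in ua) {
    px <- sum(a == x) / n
    ha <- ha - px * log(px)
  }
  for (y in ub) {
    py <- sum(b == y) / n
    hb <- hb - py * log(py)
  }
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0)
      iab <- iab + pxy * log(pxy / (sum(a == x) / n * (sum(b == y) / n)))
  }
  if (ha + hb == 0) return(1)
  2 * iab / (ha + hb)
}

# --- graph metrics ----------------------------------------------------------

oracle_transitivity <- function(adj) {
  k <- rowSums(adj)
  triples <- sum(k * (k - 1) / 2)
  a3 <- adj %*% adj %*% adj
  triangles <- sum(diag(a3)) / 6
  if (triples == 0) 0 else 3 * triangles / triples
}

oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(adj[v, ] > 0)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

oracle_diameter <- function(adj) {
  n <- nrow(adj)
  dmax <- 0
  for (s in seq_len(n)) {
    d <- oracle_bfs_dist(adj, s)
    finite <- d[is.finite(d)]
    dmax <- max(dmax, finite)
  }
  dmax
}

# Brandes-free betweenness: shortest-path counts by dynamic programming over
# BFS levels, pair contributions accumulated explicitly.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- t(vapply(seq_len(n), function(s) oracle_bfs_dist(adj, s),
                   numeric(n)))
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(dist[s, ])
    for (v in ord) {
      if (v == s || !is.finite(dist[s, v])) next
      preds <- which(adj[v, ] > 0 & dist[s, ] == dist[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  btw
}

# --- statistics -------------------------------------------------------------

oracle_hyper_p <- function(n_overlap, K, N, n) {
  tot <- choose(N, n)
  upper <- min(K, n)
  if (n_overlap > upper) return(0)
  sum(vapply(n_overlap:upper,
             function(x) choose(K, x) * choose(N - K, n - x), numeric(1))) /
    tot
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# --- enumeration ------------------------------------------------------------

# All set partitions of 1..n as restricted-growth strings.
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(code, mx) {
    i <- length(code) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- code
      return()
    }
    for (b in seq_len(mx + 1L)) recurse(c(code, b), max(mx, b))
  }
  recurse(integer(), 0L)
  out
}

# --- generators -------------------------------------------------------------

random_toy_graph <- function(n, p, seed, connected = FALSE) {
  set.seed(seed)
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
    }
    deg_ok <- all(rowSums(adj) > 0)
    if (!deg_ok) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    if (!connected || igraph::is_connected(g))
      return(list(adj = adj, graph = g))
  }
}

graph_to_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}
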