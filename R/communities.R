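#' Two-level map equation of a partition (bits per step)
#'
#' Description length of a random walk on an undirected graph under a
#' two-level coding scheme: an index codebook over module entries plus one
#' codebook per module,
#' \deqn{L(M) = q H(Q) + \sum_m p_m H(P_m),}
#' with node visit rates proportional to degree (strength when `weighted`),
#' module exit rates proportional to the edge mass leaving each module, and
#' logarithms base 2. A partition with a single module has no index codebook
#' and L equals the entropy of the visit rates.
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @param membership named (or vertex-ordered) module assignment covering all
#'   nodes.
#' @param weighted use MI edge weights instead of unit weights?
#' @return description length in bits per step.
#' @export
mapEquation <- function(net, membership, weighted = FALSE) {
  gd <- graphData(net, weighted)
  memb <- alignMembership(membership, gd$names)
  st <- moduleStats(gd, memb)
  mapEquationFromStats(st$cut, st$deg, gd$tw, gd$nodeConst)
}

# --- internal machinery -----------------------------------------------------

plogp2 <- function(x) {
  out <- x * log2(x)
  out[x <= 0] <- 0
  out
}

# Flatten an igraph into the arrays the optimizer needs. Self-loops are not
# expected (CoexNetwork forbids them) but strengths would handle them.
graphData <- function(net, weighted = FALSE) {
  g <- resolveGraph(net)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (weighted && !is.null(igraph::E(g)$weight))
    as.numeric(igraph::E(g)$weight) else rep(1, nrow(el))
  k <- numeric(n)
  nbr <- vector("list", n)
  wts <- vector("list", n)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      u <- el[e, 1]; v <- el[e, 2]
      k[u] <- k[u] + w[e]; k[v] <- k[v] + w[e]
      nbr[[u]] <- c(nbr[[u]], v); wts[[u]] <- c(wts[[u]], w[e])
      nbr[[v]] <- c(nbr[[v]], u); wts[[v]] <- c(wts[[v]], w[e])
    }
  }
  tw <- sum(k)
  nodeConst <- sum(plogp2(k[k > 0] / tw))
  list(n = n, el = el, w = w, k = k, nbr = nbr, wts = wts, tw = tw,
       nodeConst = nodeConst, names = igraph::V(g)$name)
}

alignMembership <- function(membership, node_names) {
  if (methods::is(membership, "GenePartition"))
    membership <- membership@membership
  if (!is.null(names(membership)) && !is.null(node_names)) {
    miss <- setdiff(node_names, names(membership))
    if (length(miss))
      stop("membership does not cover node(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    membership <- membership[node_names]
  }
  as.integer(as.factor(membership))
}

# Per-module total strength (deg) and external edge mass (cut).
moduleStats <- function(gd, memb) {
  n_mod <- max(memb)
  deg <- numeric(n_mod)
  cut <- numeric(n_mod)
  for (i in seq_len(gd$n)) deg[memb[i]] <- deg[memb[i]] + gd$k[i]
  if (nrow(gd$el)) {
    for (e in seq_len(nrow(gd$el))) {
      mu <- memb[gd$el[e, 1]]; mv <- memb[gd$el[e, 2]]
      if (mu != mv) {
        cut[mu] <- cut[mu] + gd$w[e]
        cut[mv] <- cut[mv] + gd$w[e]
      }
    }
  }
  list(deg = deg, cut = cut)
}

# L = plogp(qT) - 2 sum plogp(q_m) + sum plogp(p_m) - sum plogp(p_alpha)
mapEquationFromStats <- function(cut, deg, tw, nodeConst) {
  if (tw <= 0) return(0)
  q <- cut / tw
  p <- (cut + deg) / tw
  sum_q <- sum(q)
  plogp2(sum_q) - 2 * sum(plogp2(q)) + sum(plogp2(p)) - nodeConst
}

# One greedy descent: local node moves (random sweep order from the current
# RNG) until no move improves L, then aggregate modules into supernodes and
# recurse. Candidate targets are neighbouring modules plus a fresh module.
greedyDescent <- function(nbr, wts, k, self, tw, nodeConst, tol = 1e-12) {
  n <- length(k)
  memb <- seq_len(n)
  deg_m <- k
  cut_m <- k - 2 * self
  sum_cut <- sum(cut_m)

  evalL <- function() {
    q <- cut_m / tw
    p <- (cut_m + deg_m) / tw
    plogp2(sum(q)) - 2 * sum(plogp2(q)) + sum(plogp2(p)) - nodeConst
  }

  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      a <- memb[i]
      nb <- nbr[[i]]
      if (!length(nb)) next
      ww <- wts[[i]]
      mods <- memb[nb]
      wlink <- rowsum(ww, mods)
      link_mods <- as.integer(rownames(wlink))
      w_ia <- if (a %in% link_mods) wlink[match(a, link_mods), 1] else 0
      ext_i <- k[i] - 2 * self[i]
      # current contribution pieces for module a
      ca <- cut_m[a]; da <- deg_m[a]
      ca_new <- ca - ext_i + 2 * w_ia
      da_new <- da - k[i]
      cand <- setdiff(link_mods, a)
      free_mod <- 0L
      if (da_new > 1e-15 || ca_new > 1e-15) {
        # moving to a fresh module is only meaningful if a keeps members
        free_mod <- length(deg_m) + 1L
        cand <- c(cand, free_mod)
      }
      if (!length(cand)) next
      best_d <- -tol
      best_b <- 0L
      for (b in cand) {
        w_ib <- if (b != free_mod && b %in% link_mods)
          wlink[match(b, link_mods), 1] else 0
        cb <- if (b == free_mod) 0 else cut_m[b]
        db <- if (b == free_mod) 0 else deg_m[b]
        cb_new <- cb + ext_i - 2 * w_ib
        db_new <- db + k[i]
        sum_cut_new <- sum_cut + (ca_new - ca) + (cb_new - cb)
        dL <- plogp2(sum_cut_new / tw) - plogp2(sum_cut / tw) -
          2 * (plogp2(ca_new / tw) + plogp2(cb_new / tw) -
                 plogp2(ca / tw) - plogp2(cb / tw)) +
          (plogp2((ca_new + da_new) / tw) + plogp2((cb_new + db_new) / tw) -
             plogp2((ca + da) / tw) - plogp2((cb + db) / tw))
        if (dL < best_d) {
          best_d <- dL
          best_b <- b
        }
      }
      if (best_b > 0L) {
        b <- best_b
        w_ib <- if (b <= length(deg_m) && b %in% link_mods)
          wlink[match(b, link_mods), 1] else 0
        if (b > length(deg_m)) {           # fresh module
          deg_m <- c(deg_m, 0)
          cut_m <- c(cut_m, 0)
        }
        sum_cut <- sum_cut + (ca_new - ca) +
          ((cut_m[b] + ext_i - 2 * w_ib) - cut_m[b])
        cut_m[a] <- ca_new
        deg_m[a] <- da_new
        cut_m[b] <- cut_m[b] + ext_i - 2 * w_ib
        deg_m[b] <- deg_m[b] + k[i]
        memb[i] <- b
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  # compress module ids
  keep <- which(deg_m > 1e-15 | cut_m > 1e-15 | tabulate(memb, length(deg_m)) > 0)
  relab <- match(memb, sort(unique(memb)))
  n_mod <- max(relab)
  deg2 <- numeric(n_mod); cut2 <- numeric(n_mod)
  for (i in seq_len(n)) deg2[relab[i]] <- deg2[relab[i]] + k[i]
  # recompute cut on compressed labels
  cut2 <- recomputeCut(nbr, wts, self, relab)
  L <- mapEquationFromStats(cut2, deg2, tw, nodeConst)

  if (n_mod < n && n_mod > 1L) {
    agg <- aggregateGraph(nbr, wts, k, self, relab, n_mod)
    sub <- greedyDescent(agg$nbr, agg$wts, agg$k, agg$self, tw, nodeConst, tol)
    if (sub$L < L - tol) {
      memb_final <- sub$memb[relab]
      return(list(memb = memb_final, L = sub$L))
    }
  }
  list(memb = relab, L = L)
}

recomputeCut <- function(nbr, wts, self, memb) {
  n_mod <- max(memb)
  cut <- numeric(n_mod)
  for (i in seq_along(nbr)) {
    if (!length(nbr[[i]])) next
    ext <- memb[nbr[[i]]] != memb[i]
    cut[memb[i]] <- cut[memb[i]] + sum(wts[[i]][ext])
  }
  cut
}

# Condense modules into supernodes (module-level adjacency + self-loops).
aggregateGraph <- function(nbr, wts, k, self, memb, n_mod) {
  kk <- numeric(n_mod)
  ss <- numeric(n_mod)
  wmat <- matrix(0, n_mod, n_mod)
  for (i in seq_along(nbr)) {
    mi <- memb[i]
    kk[mi] <- kk[mi] + k[i]
    ss[mi] <- ss[mi] + self[i]
    if (length(nbr[[i]])) {
      for (t in seq_along(nbr[[i]])) {
        mj <- memb[nbr[[i]][t]]
        if (mj == mi) ss[mi] <- ss[mi] + wts[[i]][t] / 2
        else wmat[mi, mj] <- wmat[mi, mj] + wts[[i]][t]
      }
    }
  }
  nbr2 <- vector("list", n_mod)
  wts2 <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    nz <- which(wmat[m, ] > 0)
    nbr2[[m]] <- nz
    wts2[[m]] <- wmat[m, nz]
  }
  list(nbr = nbr2, wts = wts2, k = kk, self = ss)
}

#' Map-equation (Infomap-style) partitioning
#'
#' Two-level partition minimizing the map equation by greedy node moves
#' scored by the exact change in description length, followed by module
#' aggregation, with `n_trials` random restarts; the best trial is kept.
#' Deterministic given `seed` and `n_trials`. Setting
#' `delegate = "igraph"` routes detection through
#' [igraph::cluster_infomap()] behind the same contract; the returned
#' partition is re-scored with [mapEquation()] either way.
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @param n_trials random restarts (default 10).
#' @param seed integer seed.
#' @param weighted use MI edge weights?
#' @param delegate `"internal"` (default) or `"igraph"`.
#' @return a [GenePartition-class]; module ids are 1..n ordered by
#'   decreasing module size.
#' @export
infomapPartition <- function(net, n_trials = 10L, seed = 1L,
                             weighted = FALSE,
                             delegate = c("internal", "igraph")) {
  delegate <- match.arg(delegate)
  gd <- graphData(net, weighted)
  self <- numeric(gd$n)
  if (delegate == "igraph") {
    g <- resolveGraph(net)
    memb <- withSeed(seed, igraph::membership(igraph::cluster_infomap(
      g, nb.trials = n_trials,
      e.weights = if (weighted) igraph::E(g)$weight else NULL)))
    best <- list(memb = as.integer(memb),
                 L = NA_real_)
    st <- moduleStats(gd, best$memb)
    best$L <- mapEquationFromStats(st$cut, st$deg, gd$tw, gd$nodeConst)
  } else {
    best <- NULL
    for (t in seq_len(n_trials)) {
      res <- withSeed(stageSeed(seed, paste0("trial", t)), {
        greedyDescent(gd$nbr, gd$wts, gd$k, self, gd$tw, gd$nodeConst)
      })
      if (is.null(best) || res$L < best$L - 1e-12) best <- res
    }
  }
  memb <- relabelBySize(best$memb)
  names(memb) <- gd$names
  q <- perModuleQFromMembership(gd, memb, weighted)
  new("GenePartition", membership = memb,
      nModules = length(unique(memb)),
      codelength = best$L,
      modularityQ = sum(q),
      perModuleQ = q,
      nTrials = as.integer(n_trials), seed = as.integer(seed),
      method = if (delegate == "igraph") "igraph-infomap" else "infomap-greedy")
}

#' Score a fixed membership as a GenePartition
#'
#' Useful for ground-truth partitions or partitions from other tools.
#'
#' @inheritParams mapEquation
#' @return a [GenePartition-class] with method `"fixed"`.
#' @export
scorePartition <- function(net, membership, weighted = FALSE) {
  gd <- graphData(net, weighted)
  memb <- alignMembership(membership, gd$names)
  memb <- relabelBySize(memb)
  names(memb) <- gd$names
  st <- moduleStats(gd, memb)
  q <- perModuleQFromMembership(gd, memb, weighted)
  new("GenePartition", membership = memb,
      nModules = length(unique(memb)),
      codelength = mapEquationFromStats(st$cut, st$deg, gd$tw, gd$nodeConst),
      modularityQ = sum(q), perModuleQ = q,
      nTrials = 0L, seed = NA_integer_, method = "fixed")
}

# Contiguous ids ordered by decreasing module size (ties: first appearance).
relabelBySize <- function(memb) {
  tab <- table(memb)
  ord <- order(-as.integer(tab), match(names(tab), unique(as.character(memb))))
  map <- stats::setNames(seq_along(ord), names(tab)[ord])
  as.integer(map[as.character(memb)])
}

#' Newman modularity of a partition
#'
#' \eqn{Q = \sum_c [e_c/m - (d_c/2m)^2]} with \eqn{e_c} the intra-module edge
#' mass, \eqn{d_c} the module degree sum and m the total edge mass.
#'
#' @inheritParams mapEquation
#' @return Q in `[-1, 1]`.
#' @export
newmanModularity <- function(net, membership, weighted = FALSE) {
  sum(perModuleQ(net, membership, weighted))
}

#' Per-module modularity contributions
#'
#' Contributions `e_c/m - (d_c/2m)^2`; they sum exactly to the global Q.
#'
#' @inheritParams mapEquation
#' @return named numeric vector, one entry per module.
#' @export
perModuleQ <- function(net, membership, weighted = FALSE) {
  gd <- graphData(net, weighted)
  if (gd$tw <= 0) stop("network has no edges", call. = FALSE)
  memb <- alignMembership(membership, gd$names)
  perModuleQFromMembership(gd, memb, weighted)
}

perModuleQFromMembership <- function(gd, memb, weighted) {
  m_tot <- gd$tw / 2
  if (m_tot <= 0) stop("network has no edges", call. = FALSE)
  n_mod <- max(memb)
  e_c <- numeric(n_mod)
  d_c <- numeric(n_mod)
  for (i in seq_len(gd$n)) d_c[memb[i]] <- d_c[memb[i]] + gd$k[i]
  if (nrow(gd$el)) {
    for (e in seq_len(nrow(gd$el))) {
      mu <- memb[gd$el[e, 1]]; mv <- memb[gd$el[e, 2]]
      if (mu == mv) e_c[mu] <- e_c[mu] + gd$w[e]
    }
  }
  stats::setNames(e_c / m_tot - (d_c / (2 * m_tot))^2,
                  paste0("M", seq_len(n_mod)))
}

#' Normalized mutual information between two partitions
#'
#' Plug-in mutual information of the two label assignments on the common
#' node set, normalized by the arithmetic mean of the label entropies:
#' \eqn{NMI = I(A;B) / ((H(A)+H(B))/2)}. Nodes present in only one
#' partition are dropped (their count is reported as an attribute).
#'
#' @param partition_a,partition_b [GenePartition-class] objects or named
#'   membership vectors.
#' @return NMI in `[0, 1]`, with attribute `"n_dropped"`.
#' @export
partitionNMI <- function(partition_a, partition_b) {
  a <- if (methods::is(partition_a, "GenePartition"))
    partition_a@membership else partition_a
  b <- if (methods::is(partition_b, "GenePartition"))
    partition_b@membership else partition_b
  if (is.null(names(a)) || is.null(names(b)))
    stop("memberships must be named by gene id", call. = FALSE)
  common <- intersect(names(a), names(b))
  if (!length(common))
    stop("partitions share no nodes", call. = FALSE)
  dropped <- length(union(names(a), names(b))) - length(common)
  av <- a[common]
  bv <- b[common]
  tab <- table(av, bv) / length(common)
  ha <- -sum(xlogx(rowSums(tab)))
  hb <- -sum(xlogx(colSums(tab)))
  i_ab <- ha + hb + sum(xlogx(tab))
  val <- if (ha + hb == 0) 1 else 2 * i_ab / (ha + hb)
  val <- min(max(val, 0), 1)
  attr(val, "n_dropped") <- dropped
  val
}

#' Module membership similarity across two partitions
#'
#' Jaccard index between the gene contents of every module pair, a greedy
#' one-to-one matching (highest Jaccard first, each module matched at most
#' once) and preservation counts: how many matched pairs reach Jaccard
#' thresholds 1.0, 0.9, 0.8, 0.7, 0.6 and 0.5.
#'
#' @inheritParams partitionNMI
#' @return a [ModuleSimilarity-class].
#' @export
membershipSimilarity <- function(partition_a, partition_b) {
  a <- if (methods::is(partition_a, "GenePartition"))
    partition_a@membership else partition_a
  b <- if (methods::is(partition_b, "GenePartition"))
    partition_b@membership else partition_b
  mods_a <- split(names(a), a)
  mods_b <- split(names(b), b)
  mods_a <- mods_a[order(-lengths(mods_a))]
  mods_b <- mods_b[order(-lengths(mods_b))]
  jac <- matrix(0, length(mods_a), length(mods_b),
                dimnames = list(paste0("A", names(mods_a)),
                                paste0("B", names(mods_b))))
  for (i in seq_along(mods_a)) {
    for (j in seq_along(mods_b)) {
      inter <- length(intersect(mods_a[[i]], mods_b[[j]]))
      jac[i, j] <- inter / length(union(mods_a[[i]], mods_b[[j]]))
    }
  }
  # greedy one-to-one matching, highest Jaccard first
  work <- jac
  matching <- data.frame(module_a = character(), module_b = character(),
                         jaccard = numeric(), stringsAsFactors = FALSE)
  while (nrow(work) > 0L && ncol(work) > 0L && max(work) > -Inf) {
    idx <- which(work == max(work), arr.ind = TRUE)[1, ]
    matching <- rbind(matching, data.frame(
      module_a = rownames(work)[idx[1]],
      module_b = colnames(work)[idx[2]],
      jaccard = work[idx[1], idx[2]], stringsAsFactors = FALSE))
    work <- work[-idx[1], -idx[2], drop = FALSE]
  }
  thresholds <- c(1.0, 0.9, 0.8, 0.7, 0.6, 0.5)
  preservation <- vapply(thresholds,
                         function(t) sum(matching$jaccard >= t), integer(1))
  names(preservation) <- sprintf("ge_%.1f", thresholds)
  new("ModuleSimilarity", jaccard = jac, matching = matching,
      preservation = preservation)
}
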