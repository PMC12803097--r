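# Independent oracles used across the test suite.  These deliberately share
# no code with the package internals beyond exported constructors.

# ---- exhaustive-sum likelihood oracle ---------------------------------------
# Sums over every assignment of states to nodes and daughter corners with
# directly computed transition probabilities (Matrix::expm only).

oracle_clado_weight <- function(model, anc, l, r, M, params) {
  size <- function(b) sum(bitwAnd(b, bitwShiftL(1L, 0:15)) != 0L)
  idx <- function(b) which(bitwAnd(b, bitwShiftL(1L, 0:15)) != 0L)
  if (l == 0L || r == 0L || anc == 0L) return(0)
  base <- sub("\\+J$", "", model)
  hasj <- grepl("\\+J$", model)
  w <- 0
  if (base == "DEC") {
    if (l == anc && r == anc && size(anc) == 1L) w <- w + params$y
    sub_ok <- function(a, b) size(a) == 1L && bitwAnd(a, anc) == a && b == anc && size(anc) >= 2L
    if (sub_ok(l, r) || sub_ok(r, l)) w <- w + params$s
    vic <- bitwAnd(l, r) == 0L && bitwOr(l, r) == anc && size(anc) >= 2L &&
      min(size(l), size(r)) == 1L
    if (vic) w <- w + params$v
  } else if (base == "DIVALIKE") {
    if (l == anc && r == anc && size(anc) == 1L) w <- w + params$y
    if (bitwAnd(l, r) == 0L && bitwOr(l, r) == anc && size(anc) >= 2L) w <- w + params$v
  } else {
    if (l == anc && r == anc) w <- w + params$y
  }
  if (hasj) {
    jump_ok <- function(a, b) a == anc && size(b) == 1L && bitwAnd(b, anc) == 0L
    if (jump_ok(l, r)) w <- w + params$j * mean(M[idx(anc), idx(r)])
    if (jump_ok(r, l)) w <- w + params$j * mean(M[idx(anc), idx(l)])
  }
  w
}

oracle_lnL <- function(clade, dmm, model, params, max_size = NULL) {
  tree <- clade$tree
  n <- length(clade$realms)
  if (is.null(max_size)) max_size <- n
  states <- Filter(function(b) sum(bitwAnd(b, bitwShiftL(1L, 0:15)) != 0L) <= max_size,
                   0:(2^n - 1))
  ns <- length(states)
  ntip <- ape::Ntip(tree)
  # node ages by ape
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths[seq_len(ntip)]) - depths
  # per-stratum Q built directly from the formula
  Qk <- lapply(dmm$M, function(M) {
    Q <- matrix(0, ns, ns)
    for (a in seq_len(ns)) for (b in seq_len(ns)) {
      if (a == b) next
      A <- states[a]; B <- states[b]
      gained <- bitwAnd(B, bitwNot(A)); lost <- bitwAnd(A, bitwNot(B))
      sz <- function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:15)) != 0L)
      if (lost == 0L && sz(gained) == 1L) {
        k <- which(bitwAnd(gained, bitwShiftL(1L, 0:15)) != 0L)
        occ <- which(bitwAnd(A, bitwShiftL(1L, 0:15)) != 0L)
        if (length(occ)) Q[a, b] <- params$d * sum(M[occ, k])
      } else if (gained == 0L && sz(lost) == 1L) {
        Q[a, b] <- params$e
      }
    }
    diag(Q) <- -rowSums(Q)
    Q
  })
  # per-edge transition matrix: piecewise expm across strata (own segmentation)
  bounds <- dmm$boundaries
  edge_P <- lapply(seq_len(nrow(tree$edge)), function(k) {
    ty <- ages[tree$edge[k, 2]]; to <- ages[tree$edge[k, 1]]
    cuts <- bounds[bounds > ty & bounds < to]
    pts <- c(ty, cuts, to)
    P <- diag(ns)
    for (s in seq_len(length(pts) - 1)) {  # from old to young: left-multiply young
      mid <- (pts[s] + pts[s + 1]) / 2
      ep <- findInterval(mid, c(0, bounds)); ep <- min(max(ep, 1), length(Qk))
      P <- as.matrix(Matrix::expm(Qk[[ep]] * (pts[s + 1] - pts[s]))) %*% P
    }
    P  # rows: state at old end; cols: state at young end
  })
  # clado probabilities at a node
  clado_p <- function(node_age, anc) {
    ep <- findInterval(node_age, c(0, bounds)); ep <- min(max(ep, 1), length(Qk))
    M <- dmm$M[[ep]]
    W <- matrix(0, ns, ns)
    for (a in seq_len(ns)) for (b in seq_len(ns)) {
      W[a, b] <- oracle_clado_weight(model, states[anc], states[a], states[b], M, params)
    }
    tot <- sum(W)
    if (tot == 0) W else W / tot
  }
  # bottom-up exhaustive sum with plain loops (memoized per node x state)
  children <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
  edge_idx <- function(ch) which(tree$edge[, 2] == ch)
  tip_state <- function(tip) which(states == clade$ranges[tree$tip.label[tip]])
  lik_tab <- matrix(NA_real_, ntip + tree$Nnode, ns)
  for (tip in seq_len(ntip)) lik_tab[tip, ] <- as.numeric(seq_len(ns) == tip_state(tip))
  # general postorder: process internal nodes whose children are both done
  done <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
  while (!all(done)) {
    for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
      if (done[nd]) next
      chs <- children(nd)
      if (!all(done[chs])) next
      for (si in seq_len(ns)) {
        CP <- clado_p(ages[nd], si)
        tot <- 0
        for (a in seq_len(ns)) for (b in seq_len(ns)) {
          if (CP[a, b] == 0) next
          la <- 0
          for (x in seq_len(ns)) la <- la + edge_P[[edge_idx(chs[1])]][a, x] * lik_tab[chs[1], x]
          lb <- 0
          for (y in seq_len(ns)) lb <- lb + edge_P[[edge_idx(chs[2])]][b, y] * lik_tab[chs[2], y]
          tot <- tot + CP[a, b] * la * lb
        }
        lik_tab[nd, si] <- tot
      }
      done[nd] <- TRUE
    }
  }
  root <- ntip + 1L
  nonempty <- which(states != 0L)
  lik <- mean(lik_tab[root, nonempty])
  if (lik <= 0) -Inf else log(lik)
}

# ---- brute-force grid shortest path ----------------------------------------
# All-simple-paths minimum over a small water-cell graph (DFS, no igraph).

oracle_grid_shortest <- function(coords, edges_from, edges_to, w, src, dst) {
  adj <- lapply(seq_len(nrow(coords)), function(i) integer(0))
  wts <- lapply(seq_len(nrow(coords)), function(i) numeric(0))
  for (k in seq_along(edges_from)) {
    a <- edges_from[k]; b <- edges_to[k]
    adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], w[k])
    adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], w[k])
  }
  best <- Inf
  visited <- rep(FALSE, nrow(coords))
  dfs <- function(u, acc) {
    if (acc >= best) return()
    if (u == dst) { best <<- acc; return() }
    visited[u] <<- TRUE
    for (k in seq_along(adj[[u]])) {
      v <- adj[[u]][k]
      if (!visited[v]) dfs(v, acc + wts[[u]][k])
    }
    visited[u] <<- FALSE
  }
  dfs(src, 0)
  best
}

# ---- expected transition count for an endpoint-conditioned CTMC -------------
# E[N | X0=i, Xt=j] = sum_{k != l} q_kl int_0^t P_ik(s) P_lj(t-s) ds / P_ij(t)

oracle_expected_transitions <- function(Q, i, j, t) {
  P <- function(s) as.matrix(Matrix::expm(Q * s))
  Pij <- P(t)[i, j]
  ns <- nrow(Q)
  total <- 0
  for (k in seq_len(ns)) for (l in seq_len(ns)) {
    if (k == l || Q[k, l] <= 0) next
    f <- Vectorize(function(s) P(s)[i, k] * P(t - s)[l, j])
    total <- total + Q[k, l] * stats::integrate(f, 0, t, rel.tol = 1e-9)$value
  }
  total / Pij
}

# ---- misc -------------------------------------------------------------------

# random clade fixture over small trees / realms
random_small_clade <- function(n_tips, realms, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n_tips)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 10
  tr <- validate_phylogeny(tr)
  n <- length(realms)
  ranges <- as.integer(sample(1:(2^n - 1), n_tips, replace = TRUE))
  names(ranges) <- tr$tip.label
  clade_data(tr, ranges, realms)
}
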