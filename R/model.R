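#' Model parameters for the DEC family
#'
#' Free parameters of the dispersal-extinction-cladogenesis model family:
#' anagenetic dispersal rate `d` (events/Myr, scaled per realm pair by the
#' dispersal multiplier), per-realm extirpation rate `e` (events/Myr), and
#' founder-event weight `j` (dimensionless, 0 in the base models).  The
#' cladogenetic per-event weights `y` (narrow sympatry), `s` (subset
#' sympatry) and `v` (vicariance) are fixed at 1 by convention; only d, e and
#' j are estimated.
#'
#' @param d,e,j,y,s,v numeric scalars.
#' @return named list of class `model_params`.
#' @export
model_params <- function(d, e, j = 0, y = 1, s = 1, v = 1) {
  stopifnot(d >= 0, e >= 0, j >= 0, j < 3, y >= 0, s >= 0, v >= 0)
  structure(list(d = d, e = e, j = j, y = y, s = s, v = v), class = "model_params")
}

range_models <- c("DEC", "DEC+J", "DIVALIKE", "DIVALIKE+J", "BAYAREALIKE", "BAYAREALIKE+J")

model_base <- function(model) sub("\\+J$", "", model)
model_has_j <- function(model) grepl("\\+J$", model)

#' Anagenetic rate matrix for one stratum
#'
#' Builds the CTMC generator over the range state space for one stratum's
#' multiplier matrix: range expansion into realm k at rate
#' `d * sum_{i in R} M[i, k]` (blocked beyond the range-size cap), loss of
#' any occupied realm at rate `e`, all other transitions 0.  The empty range
#' is absorbing.
#'
#' @param params a [model_params()].
#' @param M realm-by-realm multiplier matrix for the stratum.
#' @param space a [enumerate_states()] state space.
#' @return dense rate matrix over the state space (rows sum to zero).
#' @export
build_Q <- function(params, M, space) {
  n <- space$n_realms
  if (!all(dim(M) == c(n, n))) stop("multiplier matrix dimension mismatch")
  ns <- length(space$bits)
  Q <- matrix(0, ns, ns)
  for (a in seq_len(ns)) {
    R <- space$bits[a]
    if (R == 0L) next
    occ <- bit_indices(R)
    # expansions
    if (length(occ) < space$max_size) {
      for (k in setdiff(seq_len(n), occ)) {
        tgt <- bitwOr(R, bitwShiftL(1L, k - 1L))
        Q[a, state_pos(space, tgt)] <- params$d * sum(M[occ, k])
      }
    }
    # contractions
    for (i in occ) {
      tgt <- bitwAnd(R, bitwNot(bitwShiftL(1L, i - 1L)))
      Q[a, state_pos(space, tgt)] <- params$e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Cladogenetic event table
#'
#' Enumerates, per ancestral range, the daughter-range pairs each model
#' allows, with their event type and normalized probability:
#'
#' * DEC: narrow sympatry (single-realm ancestor copies), subset sympatry
#'   (one daughter a single realm nested in the ancestor, the other the full
#'   ancestor), and narrow vicariance (one daughter a single realm, the other
#'   the rest);
#' * DIVALIKE: narrow sympatry plus vicariance splits of any size;
#' * BAYAREALIKE: pure copying (both daughters inherit the full range);
#' * +J variants add founder events: one daughter jumps to a single realm
#'   outside the ancestral range, weighted `j` times the mean multiplier
#'   from the occupied realms to the destination.
#'
#' Weights (`y`, `s`, `v`, founder) are normalized to probabilities within
#' each ancestral range.
#'
#' @param model one of `"DEC"`, `"DEC+J"`, `"DIVALIKE"`, `"DIVALIKE+J"`,
#'   `"BAYAREALIKE"`, `"BAYAREALIKE+J"`.
#' @param params a [model_params()].
#' @param space state space.
#' @param M multiplier matrix applying at the node (founder weights only).
#' @return data.frame with columns `anc`, `left`, `right` (bitmasks), `type`,
#'   `weight`, `prob`, plus position columns `anc_pos`, `left_pos`,
#'   `right_pos`.
#' @export
build_clado_table <- function(model, params, space, M = NULL) {
  model <- match.arg(model, range_models)
  if (is.null(M)) M <- matrix(1, space$n_realms, space$n_realms)
  ev <- clado_structure(model, space, M)
  ev$prob <- clado_probs(ev, params)
  ev$weight <- ev$prob  # kept for readability of returned tables
  w <- c(narrow_sympatry = params$y, copying = params$y,
         subset_sympatry = params$s, vicariance = params$v, founder = params$j)
  ev$weight <- unname(w[ev$type]) * ev$mult
  ev
}

# structural enumeration (model-dependent, parameter-free except the founder
# mean multiplier, returned in `mult`)
clado_structure <- function(model, space, M) {
  base <- model_base(model)
  has_j <- model_has_j(model)
  anc <- integer(0); left <- integer(0); right <- integer(0)
  type <- character(0); mult <- numeric(0)
  add <- function(a, l, r, ty, m = 1) {
    anc <<- c(anc, a); left <<- c(left, l); right <<- c(right, r)
    type <<- c(type, ty); mult <<- c(mult, m)
  }
  n <- space$n_realms
  for (R in space$bits) {
    if (R == 0L) next
    occ <- bit_indices(R)
    sz <- length(occ)
    if (base == "DEC") {
      if (sz == 1L) {
        add(R, R, R, "narrow_sympatry")
      } else {
        for (i in occ) {
          im <- bitwShiftL(1L, i - 1L)
          add(R, im, R, "subset_sympatry"); add(R, R, im, "subset_sympatry")
        }
        # narrow vicariance: every ordered bipartition with a single-realm side
        for (S in proper_subsets(occ)) {
          rest <- bitwAnd(R, bitwNot(S))
          if (min(range_size(S), range_size(rest)) == 1L) add(R, S, rest, "vicariance")
        }
      }
    } else if (base == "DIVALIKE") {
      if (sz == 1L) {
        add(R, R, R, "narrow_sympatry")
      } else {
        for (S in proper_subsets(occ)) {
          rest <- bitwAnd(R, bitwNot(S))
          add(R, S, rest, "vicariance")
        }
      }
    } else {  # BAYAREALIKE: copying only (narrow sympatry when single-realm)
      add(R, R, R, if (sz == 1L) "narrow_sympatry" else "copying")
    }
    if (has_j) {
      for (k in setdiff(seq_len(n), occ)) {
        km <- bitwShiftL(1L, k - 1L)
        m <- mean(M[occ, k])
        add(R, R, km, "founder", m); add(R, km, R, "founder", m)
      }
    }
  }
  df <- data.frame(anc = anc, left = left, right = right, type = type,
                   mult = mult, stringsAsFactors = FALSE)
  df$anc_pos <- state_pos(space, df$anc)
  df$left_pos <- state_pos(space, df$left)
  df$right_pos <- state_pos(space, df$right)
  df
}

# all ordered nonempty proper sub-bitmasks of the realms in `occ`
proper_subsets <- function(occ) {
  n <- length(occ)
  out <- integer(0)
  for (m in seq_len(2L^n - 2L)) {
    picked <- occ[bit_indices(m)]
    out <- c(out, as.integer(sum(bitwShiftL(1L, picked - 1L))))
  }
  out
}

# propagator factory: fast eigendecomposition path with expm fallback
make_propagator <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  Vi <- NULL
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      # accept only a well-conditioned eigenbasis
      kap <- max(abs(eg$vectors)) * max(abs(Vi))
      use_eigen <- is.finite(kap) && kap < 1e8
    }
  }
  function(t) {
    if (t <= 0) return(diag(nrow(Q)))
    if (use_eigen) {
      P <- Re(eg$vectors %*% (exp(eg$values * t) * Vi))
      if (all(abs(rowSums(P) - 1) < 1e-8) && min(P) > -1e-8) {
        P[P < 0] <- 0
        return(P)
      }
    }
    as.matrix(Matrix::expm(Q * t))
  }
}

# split an edge [age_young, age_old] at stratum boundaries; returns segments
# youngest first: data.frame(young, old, epoch)
edge_segments <- function(dmm, age_young, age_old) {
  cuts <- dmm$boundaries[dmm$boundaries > age_young & dmm$boundaries < age_old]
  pts <- c(age_young, cuts, age_old)
  mids <- (pts[-1] + pts[-length(pts)]) / 2
  data.frame(young = pts[-length(pts)], old = pts[-1], epoch = epoch_at(dmm, mids))
}

# precomputed structures reused across likelihood evaluations during fitting:
# state space, postorder traversal, branch segmentation by stratum, node
# epochs, and the parameter-free cladogenesis structure per stratum
lik_context <- function(clade, dmm, model, max_size = NULL) {
  tree <- clade$tree
  n <- length(clade$realms)
  if (is.null(max_size)) max_size <- n
  space <- enumerate_states(n, max_size)
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  if (max(ages) > max(dmm$boundaries) + 1e-9) {
    stop("DMM cap (", max(dmm$boundaries), " Ma) is younger than the root age")
  }
  post <- reorder(tree, "postorder")
  kids <- lapply(split(post$edge[, 2], post$edge[, 1]), identity)
  if (any(lengths(kids) != 2L)) stop("tree must be strictly bifurcating")
  segs <- lapply(seq_len(nrow(post$edge)), function(k) {
    edge_segments(dmm, ages[post$edge[k, 2]], ages[post$edge[k, 1]])
  })
  structs <- lapply(dmm$M, function(M) clado_structure(model, space, M))
  list(clade = clade, dmm = dmm, model = model, space = space, ntip = ntip,
       ages = ages, edge = post$edge, segs = segs, kids = kids,
       node_epoch = epoch_at(dmm, ages), structs = structs,
       tip_pos = state_pos(space, clade$ranges[tree$tip.label]))
}

clado_probs <- function(struct, params) {
  w <- c(narrow_sympatry = params$y, copying = params$y,
         subset_sympatry = params$s, vicariance = params$v, founder = params$j)
  weight <- unname(w[struct$type]) * struct$mult
  tot <- stats::ave(weight, struct$anc, FUN = sum)
  tot[tot == 0] <- 1
  weight / tot
}

lnL_context <- function(ctx, params, details = FALSE) {
  space <- ctx$space
  ns <- length(space$bits)
  props <- lapply(ctx$dmm$M, function(M) make_propagator(build_Q(params, M, space)))
  probs <- lapply(ctx$structs, clado_probs, params = params)
  n_node <- ctx$ntip + length(ctx$kids)
  L <- matrix(0, n_node, ns)
  L[cbind(seq_len(ctx$ntip), ctx$tip_pos)] <- 1
  B <- matrix(0, n_node, ns)
  logscale <- 0
  combine <- function(nd) {
    ep <- ctx$node_epoch[nd]
    st <- ctx$structs[[ep]]
    chs <- ctx$kids[[as.character(nd)]]
    contrib <- probs[[ep]] * B[chs[1], st$left_pos] * B[chs[2], st$right_pos]
    out <- numeric(ns)
    agg <- rowsum(contrib, st$anc_pos)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  for (k in seq_len(nrow(ctx$edge))) {
    ch <- ctx$edge[k, 2]
    if (ch > ctx$ntip) L[ch, ] <- combine(ch)
    v <- L[ch, ]
    segs <- ctx$segs[[k]]
    for (s in seq_len(nrow(segs))) {  # youngest segment applied first
      v <- props[[segs$epoch[s]]](segs$old[s] - segs$young[s]) %*% v
    }
    sc <- sum(v)
    if (sc <= 0 || !is.finite(sc)) {
      return(if (details) list(lnL = -Inf) else -Inf)
    }
    B[ch, ] <- v / sc
    logscale <- logscale + log(sc)
  }
  root <- ctx$ntip + 1L
  L[root, ] <- combine(root)
  nonempty <- space$bits != 0L
  lik <- mean(L[root, nonempty])
  lnL <- if (lik <= 0 || !is.finite(lik)) -Inf else log(lik) + logscale
  if (!details) return(lnL)
  list(lnL = lnL, L = L, B = B, props = props, probs = probs, params = params)
}

#' Log-likelihood of tip ranges under a DEC-family model
#'
#' Felsenstein pruning over the range state space with piecewise-constant
#' rates: each branch is split at stratum boundaries and propagated with the
#' matrix exponential of that stratum's generator; cladogenetic mixing at
#' each internal node uses the event table of the stratum containing the node
#' age.  The root likelihood is the mean over all non-empty root states (flat
#' root prior).  Per-branch rescaling guards against underflow on large
#' trees.
#'
#' @param clade a [clade_data()].
#' @param dmm a [stratified_dmm()] (e.g. [uniform_dmm()]); its final boundary
#'   must reach the root age.
#' @param model model name, see [build_clado_table()].
#' @param params a [model_params()].
#' @param max_size optional range-size cap (default: number of realms).
#' @return the log-likelihood (scalar; `-Inf` if the data are impossible
#'   under the parameters).
#' @export
loglikelihood <- function(clade, dmm, model, params, max_size = NULL) {
  ctx <- lik_context(clade, dmm, model, max_size)
  lnL_context(ctx, params)
}
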