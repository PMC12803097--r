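# shared in-code fixtures

realms2 <- realm_set(c("A", "B"))
realms3 <- realm_set(c("A", "B", "C"))

# a 2-tip cherry with both tips in realm A
cherry_clade <- function(realms = realms2) {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  clade_data(tr, c(a = 1L, b = 1L), realms)
}

# small mask helpers: a single row of all-water cells on the equator
row_mask <- function(n_cells, lon_step = 1, land_cols = integer(0)) {
  lon <- seq(0, by = lon_step, length.out = n_cells)
  water <- matrix(TRUE, 1, n_cells)
  water[1, land_cols] <- FALSE
  water_mask(lon, 0, water)
}

models6 <- c("DEC", "DEC+J", "DIVALIKE", "DIVALIKE+J", "BAYAREALIKE", "BAYAREALIKE+J")

# draw a (tree, ranges) pair conditioned on the forward simulation succeeding:
# trees whose shape cannot yield all-extant, non-empty tip ranges within the
# resample cap are redrawn with the next seed
sim_conditioned <- function(n_tips, realms, dmm, model, params, seed,
                            lambda = 0.5, mu = 0, tries = 25L) {
  for (k in seq_len(tries) - 1L) {
    tr <- sim_tree(n_tips, lambda = lambda, mu = mu, seed = seed + k)
    sim <- tryCatch(
      sim_ranges(tr, realms, dmm, model, params, seed = seed + 1000L + k),
      error = function(e) NULL)
    if (!is.null(sim)) return(sim)
  }
  stop("no viable forward simulation in ", tries, " tree draws")
}

# extract igraph-free edge list of a water mask for the brute-force oracle
mask_graph <- function(mask) {
  wet <- which(mask$water, arr.ind = TRUE)
  coords <- cbind(mask$lon[wet[, 2]], mask$lat[wet[, 1]])
  nr <- nrow(mask$water); nc <- ncol(mask$water)
  cellid <- matrix(0L, nr, nc); cellid[wet] <- seq_len(nrow(wet))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    for (u in seq_len(nrow(wet))) {
      i2 <- wet[u, 1] + di; j2 <- wet[u, 2] + dj
      if (mask$wrap) j2 <- ((j2 - 1L) %% nc) + 1L
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      v <- cellid[i2, j2]
      if (v > u) {
        from <- c(from, u); to <- c(to, v)
        w <- c(w, geosphere::distHaversine(coords[u, ], coords[v, ]) / 1000)
      }
    }
  }
  list(coords = coords, from = from, to = to, w = w)
}
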