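# Independent oracles and hand-built fixtures shared across test files.
# Everything here is deliberately naive (double loops, exhaustive
# enumeration) and independent of the package's optimized code paths.

fcc_offsets_ref <- rbind(
  c( 1,  1, 0), c( 1, -1, 0), c(-1,  1, 0), c(-1, -1, 0),
  c( 1, 0,  1), c( 1, 0, -1), c(-1, 0,  1), c(-1, 0, -1),
  c(0,  1,  1), c(0,  1, -1), c(0, -1,  1), c(0, -1, -1))

site_key <- function(p, L) (p[1] %% L) + L * ((p[2] %% L) + L * (p[3] %% L))

# brute-force double loop over all monomers and their 12 neighbour images
brute_energy <- function(state) {
  L <- state$L; co <- state$coords; sp <- state$species
  occ <- integer(L^3)
  for (m in seq_len(nrow(co))) occ[site_key(co[m, ], L) + 1L] <- m
  e <- 0
  for (m in which(sp == 1)) for (k in 1:12) {
    o <- occ[site_key(co[m, ] + fcc_offsets_ref[k, ], L) + 1L]
    if (o == 0 || sp[o] == 2) e <- e + 1
  }
  e
}

# brute-force all-pairs chain contact graph -> cluster membership
brute_clusters <- function(state) {
  L <- state$L; co <- state$coords; sp <- state$species
  len <- state$chain_len
  n_ch <- state$n_chains
  chain_of <- rep(seq_len(n_ch), each = len)
  adj <- diag(n_ch) > 0
  a_idx <- which(sp == 1)
  for (i in a_idx) for (j in a_idx) {
    if (chain_of[i] == chain_of[j]) next
    for (k in 1:12) {
      if (site_key(co[i, ] + fcc_offsets_ref[k, ], L) == site_key(co[j, ], L)) {
        adj[chain_of[i], chain_of[j]] <- TRUE
        adj[chain_of[j], chain_of[i]] <- TRUE
        break
      }
    }
  }
  # transitive closure by repeated multiplication (tiny fixtures only)
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  membership <- integer(n_ch)
  next_id <- 0L
  for (c in seq_len(n_ch)) {
    if (membership[c] == 0L) {
      next_id <- next_id + 1L
      membership[adj[c, ]] <- next_id
    }
  }
  membership
}

# exhaustive enumeration of directed self-avoiding 4-walks of an all-A
# tetramer on the L = 4 FCC box, with their contact energies
enumerate_tetramer <- function(L = 4) {
  g <- as.matrix(expand.grid(0:(L - 1), 0:(L - 1), 0:(L - 1)))
  sites <- g[rowSums(g) %% 2 == 0, , drop = FALSE]
  energy_of <- function(path) {
    occ <- integer(L^3)
    for (m in 1:4) occ[site_key(path[m, ], L) + 1L] <- m
    e <- 0
    for (m in 1:4) for (k in 1:12)
      if (occ[site_key(path[m, ] + fcc_offsets_ref[k, ], L) + 1L] == 0) e <- e + 1
    e
  }
  energies <- integer(0)
  for (i in seq_len(nrow(sites))) {
    p1 <- sites[i, ]
    for (k2 in 1:12) {
      p2 <- p1 + fcc_offsets_ref[k2, ]
      for (k3 in 1:12) {
        p3 <- p2 + fcc_offsets_ref[k3, ]
        if (site_key(p3, L) == site_key(p1, L)) next
        for (k4 in 1:12) {
          p4 <- p3 + fcc_offsets_ref[k4, ]
          if (site_key(p4, L) == site_key(p1, L) ||
              site_key(p4, L) == site_key(p2, L)) next
          energies <- c(energies, energy_of(rbind(p1, p2, p3, p4)))
        }
      }
    }
  }
  energies
}

make_state <- function(L, coords, species, chain_len) {
  storage.mode(coords) <- "integer"
  micellkit:::new_lattice_state(L, coords, as.integer(species), as.integer(chain_len))
}

# a straight filament chain: x increases by 1 per step, y alternates 0/1,
# wrapping the L = n box in x (a torus-spanning cylinder of thickness 1)
filament_state <- function(n = 26L, species = rep(1L, n)) {
  co <- cbind(0:(n - 1), (0:(n - 1)) %% 2, rep(0L, n))
  make_state(as.integer(n), co, species, n)
}

# deterministic compact self-avoiding walk confined to a ball, found by
# depth-first search with a fixed neighbour order
confined_chain <- function(length, centre, radius, L, occupied = NULL) {
  occ <- new.env(parent = emptyenv())
  for (p in occupied) assign(as.character(site_key(p, L)), TRUE, envir = occ)
  inside <- function(p) sum((p - centre)^2) <= radius^2
  path <- matrix(NA_integer_, length, 3)
  found <- FALSE
  dfs <- function(p, depth) {
    if (found) return()
    path[depth, ] <<- p
    assign(as.character(site_key(p, L)), TRUE, envir = occ)
    if (depth == length) { found <<- TRUE; return() }
    for (k in 1:12) {
      q <- p + fcc_offsets_ref[k, ]
      if (!inside(q)) next
      if (!is.null(occ[[as.character(site_key(q, L))]])) next
      dfs(q, depth + 1)
      if (found) return()
    }
    rm(list = as.character(site_key(p, L)), envir = occ)
  }
  span <- ceiling(radius)
  cand <- as.matrix(expand.grid(-span:span, -span:span, -span:span))
  cand <- cand[order(rowSums(cand^2)), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    start <- centre + cand[i, ]
    if (sum(start) %% 2 != 0 || !inside(start)) next
    if (!is.null(occ[[as.character(site_key(start, L))]])) next
    dfs(start, 1)
    if (found) break
  }
  if (!found) stop("no confined walk found; enlarge the ball")
  path
}

# two compact blobs (one per ball) of `chains_per_blob` chains each
blob_state <- function(L = 20L, chain_len = 13L, chains_per_blob = 2L) {
  centres <- list(c(5L, 5L, 5L), c(14L, 14L, 14L))
  coords <- NULL
  occupied <- list()
  for (ctr in centres) {
    for (i in seq_len(chains_per_blob)) {
      p <- confined_chain(chain_len, ctr, 3.2, L, occupied)
      occupied <- c(occupied, lapply(seq_len(nrow(p)), function(j) p[j, ]))
      coords <- rbind(coords, p)
    }
  }
  make_state(L, coords, rep(1L, nrow(coords)), chain_len)
}

# branched network: an x-spanning filament (y in {0,1}, z = 0) plus two
# z-spanning filaments at y = 2 that touch it diagonally at separated
# junctions; the cluster percolates in x and z with two skeleton branches
network_state <- function() {
  L <- 26L
  n <- 26L
  xline <- cbind(0:(n - 1), (0:(n - 1)) %% 2, rep(0L, n))
  zline <- function(x0) {                # x0 even; parity x + 2 + z even
    z <- 0:(n - 1)
    cbind(x0 + z %% 2, rep(2L, n), z)
  }
  co <- rbind(xline, zline(4L), zline(16L))
  stopifnot(!anyDuplicated(apply(co, 1, site_key, L = L)))
  make_state(L, co, rep(1L, nrow(co)), n)
}
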