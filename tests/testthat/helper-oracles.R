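# Independent oracles and small builders shared across tests. These
# re-derive expected results by brute force, separately from the package's
# own code paths.

# --- molecular graph oracle helpers (ChemmineOB/ChemmineR/igraph direct) ---

# parse a SMILES into an igraph with a `symbol` vertex attribute, bypassing
# the package's internal parser
oracle_graph <- function(smiles) {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))
  sset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdf)))
  ab <- ChemmineR::atomblock(sset[[1]])
  bb <- ChemmineR::bondblock(sset[[1]])
  g <- igraph::make_empty_graph(n = nrow(ab), directed = FALSE)
  if (!is.null(bb) && nrow(bb) > 0) {
    g <- igraph::add_edges(g, rbind(as.integer(bb[, 1]), as.integer(bb[, 2])))
  }
  igraph::set_vertex_attr(g, "symbol", value = sub("_[0-9]+$", "", rownames(ab)))
}

# brute-force major chain: enumerate every simple path, rank by
# (length, heteroatom count), return the canonical SMILES of the best path
# (ties: lexicographically smallest canonical SMILES, C locale). Only valid
# for acyclic single-bonded molecules over C/N/O/S, where a path's SMILES
# is just its atom symbols concatenated.
oracle_major_chain <- function(smiles) {
  g <- oracle_graph(smiles)
  sym <- igraph::vertex_attr(g, "symbol")
  n <- igraph::vcount(g)
  if (n == 1L) return(canonicalize_smiles(sym))
  paths <- list()
  for (v in seq_len(n)) {
    ps <- igraph::all_simple_paths(g, from = v)
    paths <- c(paths, lapply(ps, as.integer))
  }
  len <- vapply(paths, length, integer(1))
  het <- vapply(paths, function(p) sum(!(sym[p] %in% "C")), integer(1))
  best <- len == max(len)
  best[best] <- het[best] == max(het[best])
  cand <- unique(vapply(paths[best], function(p) paste(sym[p], collapse = ""),
                        character(1)))
  sort(canonicalize_smiles(cand), method = "radix")[1]
}

# --- layout oracles (pure R, no package layout code) ---

oracle_overlap <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  ox <- min(ax + aw / 2, bx + bw / 2) - max(ax - aw / 2, bx - bw / 2)
  oy <- min(ay + ah / 2, by + bh / 2) - max(ay - ah / 2, by - bh / 2)
  max(ox, 0) * max(oy, 0)
}

oracle_score <- function(cx, cy, cw, ch, placed, w_overlap, w_distance) {
  s <- 0
  for (j in seq_len(NROW(placed))) {
    s <- s + w_overlap * oracle_overlap(cx, cy, cw, ch, placed$x[j],
                                        placed$y[j], placed$w[j], placed$h[j])
    s <- s + w_distance * sqrt((cx - placed$x[j])^2 + (cy - placed$y[j])^2)
  }
  s
}

# exhaustive replay of the greedy sequence: at each step, minimize the score
# over all in-canvas grid points by full enumeration (row-major; ties keep
# the first)
oracle_greedy <- function(w, h, canvas_w, canvas_h, gx, gy, w_overlap,
                          w_distance) {
  ord <- order(-(w * h), seq_along(w))
  w <- w[ord]; h <- h[ord]
  placed <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                       h = numeric(0))
  for (i in seq_along(w)) {
    if (i == 1L) {
      placed[1, ] <- c(canvas_w / 2, canvas_h / 2, w[1], h[1])
      next
    }
    best <- Inf; bx <- NA; by <- NA
    for (cy in gy) for (cx in gx) {
      if (cx - w[i] / 2 < 0 || cx + w[i] / 2 > canvas_w ||
          cy - h[i] / 2 < 0 || cy + h[i] / 2 > canvas_h) next
      s <- oracle_score(cx, cy, w[i], h[i], placed, w_overlap, w_distance)
      if (s < best) { best <- s; bx <- cx; by <- cy }
    }
    placed[i, ] <- c(bx, by, w[i], h[i])
  }
  placed
}

# power-law sized random rectangle instances for layout stress tests
random_items <- function(n, seed, base = 40, exponent = 1.2) {
  withr::with_seed(seed, {
    mag <- base * (seq_len(n) / n)^(-exponent / 2)
    mag <- pmin(mag, 6 * base)
    ar <- runif(n, 0.6, 1.7)
    cloud_items(sprintf("it%03d", seq_len(n)),
                width = sample(mag) * sqrt(ar),
                height = sample(mag) / sqrt(ar))
  })
}

# canvas sized to a multiple of the total item area, same aspect as 10:7
canvas_for <- function(items, area_factor) {
  a <- sum(items$width * items$height) * area_factor
  c(width = sqrt(a * 10 / 7), height = sqrt(a * 7 / 10))
}
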