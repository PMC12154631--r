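# Hand-built residues/structures and independent brute-force oracles.
# The oracles use plain double loops and scalar distances on purpose: they
# must stay independent of the package's vectorized implementation.

mk_res <- function(resno, names, altlocs, coords, chain = "A",
                   resname = "SER", occupancy = NULL) {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  stopifnot(length(names) == nrow(coords), length(altlocs) == nrow(coords))
  if (is.null(occupancy)) {
    occupancy <- ifelse(altlocs == "", 1, 0.5)
  }
  atoms <- data.frame(
    name = names, element = substr(names, 1, 1), altloc = altlocs,
    occupancy = occupancy,
    x = coords[, 1], y = coords[, 2], z = coords[, 3], b = 0,
    is_backbone = names %in% c("N", "CA", "C", "O"),
    stringsAsFactors = FALSE
  )
  labs <- sort(unique(altlocs[altlocs != ""]))
  list(chain = chain, resno = resno, icode = "",
       key = paste0(chain, ":", resno), resname = resname,
       aa1 = "S", atoms = atoms, altlocs = labs,
       n_conformers = max(1L, length(labs)),
       n_unique_atoms = length(unique(names)))
}

mk_structure <- function(residues, id = "toy") {
  names(residues) <- vapply(residues, function(r) r$key, character(1))
  structure(list(structure_id = id, resolution = NA_real_,
                 chains = sort(unique(vapply(residues, function(r) r$chain,
                                             character(1)))),
                 residues = residues),
            class = "mc_structure")
}

adist1 <- function(a, b) sqrt(sum((a - b)^2))

oracle_spatial_weight <- function(resA, resB, cutoff = 4,
                                  min_conformers = 2, mode = "one") {
  ncA <- resA$n_conformers
  ncB <- resB$n_conformers
  ok <- if (mode == "one") max(ncA, ncB) >= min_conformers
        else min(ncA, ncB) >= min_conformers
  if (!ok) return(0)
  A <- resA$atoms[resA$atoms$altloc != "", , drop = FALSE]
  B <- resB$atoms[resB$atoms$altloc != "", , drop = FALSE]
  P <- 0
  if (nrow(A) > 0 && nrow(B) > 0) {
    for (a in seq_len(nrow(A))) {
      for (b in seq_len(nrow(B))) {
        d <- adist1(c(A$x[a], A$y[a], A$z[a]), c(B$x[b], B$y[b], B$z[b]))
        if (d <= cutoff) P <- P + 1
      }
    }
  }
  if (P == 0) return(0)
  P / (length(unique(resA$atoms$name)) + length(unique(resB$atoms$name)))
}

oracle_backbone_pairs <- function(resA, resB, cutoff = 4) {
  A <- resA$atoms[resA$atoms$is_backbone & resA$atoms$altloc != "", ,
                  drop = FALSE]
  B <- resB$atoms[resB$atoms$is_backbone & resB$atoms$altloc != "", ,
                  drop = FALSE]
  n <- 0
  for (a in seq_len(nrow(A))) {
    for (b in seq_len(nrow(B))) {
      d <- adist1(c(A$x[a], A$y[a], A$z[a]), c(B$x[b], B$y[b], B$z[b]))
      if (d <= cutoff) n <- n + 1
    }
  }
  n
}

# all-pairs network oracle, no spatial indexing
oracle_network <- function(st, cutoff = 4, min_conformers = 2,
                           mode = "one") {
  res <- st$residues
  n <- length(res)
  rows <- list()
  has_bb_alt <- function(r) {
    bb <- r$atoms$is_backbone & r$atoms$altloc != ""
    length(unique(r$atoms$altloc[bb])) >= 2
  }
  seq_adj <- function(a, b) {
    res[[a]]$chain == res[[b]]$chain && b == a + 1 &&
      (res[[b]]$resno - res[[a]]$resno) <= 1
  }
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        if (seq_adj(a, b)) next
        w <- oracle_spatial_weight(res[[a]], res[[b]], cutoff,
                                   min_conformers, mode)
        if (w > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            i = res[[a]]$key, j = res[[b]]$key, weight = w,
            provenance = "spatial", stringsAsFactors = FALSE)
        }
      }
    }
    for (a in 1:(n - 1)) {
      b <- a + 1
      if (!seq_adj(a, b)) next
      if (!has_bb_alt(res[[a]]) || !has_bb_alt(res[[b]])) next
      B <- oracle_backbone_pairs(res[[a]], res[[b]], cutoff)
      if (B > 0) {
        w <- B / (res[[a]]$n_unique_atoms + res[[b]]$n_unique_atoms)
        rows[[length(rows) + 1]] <- data.frame(
          i = res[[a]]$key, j = res[[b]]$key, weight = w,
          provenance = "sequential", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(i = character(), j = character(), weight = numeric(),
                      provenance = character()))
  }
  out <- do.call(rbind, rows)
  out[order(match(out$i, names(res)), match(out$j, names(res))), ]
}

expect_same_network <- function(net, oracle, tol = 1e-9) {
  key <- function(df) paste(df$i, df$j)
  expect_setequal(key(net$edges), key(oracle))
  m <- match(key(oracle), key(net$edges))
  expect_equal(net$edges$weight[m], oracle$weight, tolerance = tol)
  expect_equal(net$edges$provenance[m], oracle$provenance)
}

# exhaustive modularity oracle; modularity computed from scratch
oracle_modularity <- function(edges, membership) {
  m <- sum(edges$weight)
  if (m == 0) return(0)
  deg <- tapply(c(edges$weight, edges$weight),
                c(as.character(edges$i), as.character(edges$j)), sum)
  q <- 0
  for (comm in unique(membership)) {
    members <- names(membership)[membership == comm]
    inside <- as.character(edges$i) %in% members &
      as.character(edges$j) %in% members
    w_in <- sum(edges$weight[inside])
    d_c <- sum(deg[names(deg) %in% members])
    q <- q + w_in / m - (d_c / (2 * m))^2
  }
  q
}

# best partition over all set partitions (restricted growth strings);
# feasible for <= 8 nodes
oracle_best_partition <- function(edges, nodes) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  stopifnot(n <= 8)
  best <- list(q = -Inf, membership = NULL)
  assign_next <- function(labels, k, mx) {
    if (k > n) {
      mem <- stats::setNames(labels, nodes)
      q <- oracle_modularity(edges, mem)
      if (q > best$q + 1e-12) best <<- list(q = q, membership = mem)
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1)) {
      assign_next(c(labels, v), k + 1, max(mx, v))
    }
  }
  assign_next(integer(0), 1, 0)
  best
}

# best bipartition (plus the trivial single community), for larger graphs
oracle_best_bipartition <- function(edges, nodes) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  best <- list(q = oracle_modularity(
    edges, stats::setNames(rep(1, n), nodes)),
    membership = stats::setNames(rep(1, n), nodes))
  for (mask in 1:(2^(n - 1) - 1)) {
    side <- as.integer(intToBits(mask))[1:n] + 1L
    mem <- stats::setNames(side, nodes)
    q <- oracle_modularity(edges, mem)
    if (q > best$q + 1e-12) best <- list(q = q, membership = mem)
  }
  best
}

same_partition <- function(a, b) {
  a <- a[sort(names(a))]
  b <- b[sort(names(b))]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# small sum_network from an explicit edge table
mk_sum_network <- function(i, j, weight) {
  edges <- data.frame(i = i, j = j, weight = weight)
  structure(list(edges = edges, nodes = sort(unique(c(i, j))),
                 n_structures = 1, structure_ids = "x",
                 averaged = FALSE, ref_of_col = NULL),
            class = "sum_network")
}

clique_edges <- function(nodes, weight = 1) {
  pairs <- t(utils::combn(nodes, 2))
  data.frame(i = pairs[, 1], j = pairs[, 2], weight = weight)
}

barbell <- function(n1 = 5, n2 = 5, bridge_w = 1) {
  left <- clique_edges(1:n1)
  right <- clique_edges(n1 + (1:n2))
  bridge <- data.frame(i = n1, j = n1 + 1, weight = bridge_w)
  e <- rbind(left, right, bridge)
  mk_sum_network(e$i, e$j, e$weight)
}

# assemble a multinetwork from an in-memory synthetic family
assemble_multinetwork <- function(fam, params = rin_params()) {
  ids <- names(fam$structures)
  aligned <- lapply(ids, function(id) {
    log_normalize(align_rin(build_network(fam$structures[[id]], params),
                            fam$maps[[id]]))
  })
  build_multinetwork(aligned, fam$metadata,
                     ref_of_col = fam$maps[[fam$reference_id]]$ref_of_col)
}

# aligned network from an explicit edge table (for multinetwork algebra)
mk_aligned <- function(id, i, j, weight) {
  structure(list(structure_id = id,
                 edges = data.frame(i = as.integer(i), j = as.integer(j),
                                    weight = weight),
                 nodes = sort(unique(c(i, j))), n_dropped = 0, norm = NULL),
            class = "aligned_rin")
}
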