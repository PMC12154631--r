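#' Parameters for residue interaction network construction
#'
#' @param contact_cutoff heavy-atom distance cutoff in Angstrom for an atom
#'   pair to count as a contact (default 4.0).
#' @param min_conformers minimum number of alternate conformations a residue
#'   needs to contribute altloc atoms (default 2).
#' @param min_conformers_mode `"one"` (default): at least one residue of a
#'   pair must reach `min_conformers` (a flexible residue packing against a
#'   rigid one is still a coupling candidate); `"both"`: both must.
#' @param size_normalization `"sum_atoms"` (default): contact counts divided
#'   by the sum of the two residues' unique heavy-atom counts;
#'   `"geometric_mean"`: divided by the geometric mean of the two counts.
#' @return list of class `rin_params`.
#' @export
rin_params <- function(contact_cutoff = 4.0, min_conformers = 2L,
                       min_conformers_mode = c("one", "both"),
                       size_normalization = c("sum_atoms", "geometric_mean")) {
  stopifnot(contact_cutoff > 0, min_conformers >= 1)
  structure(list(
    contact_cutoff = contact_cutoff,
    min_conformers = as.integer(min_conformers),
    min_conformers_mode = match.arg(min_conformers_mode),
    size_normalization = match.arg(size_normalization)
  ), class = "rin_params")
}

.size_norm <- function(uA, uB, params) {
  switch(params$size_normalization,
         sum_atoms = uA + uB,
         geometric_mean = sqrt(uA * uB))
}

#' Spatial contact weight between two residues
#'
#' Counts atom pairs between the alternate-conformation atoms (non-blank
#' altloc label) of two residues that lie within the contact cutoff; each
#' distinct (atom name, altloc) x (atom name, altloc) pair counts once. The
#' count is normalized by residue size: `P / (U_A + U_B)` where `U` is the
#' number of unique heavy-atom names in each residue. At least one residue
#' (or both, see [rin_params()]) must have `min_conformers` or more alternate
#' conformations, otherwise the weight is 0. Sequence-adjacent residues are
#' excluded from spatial weighting by [build_network()] and handled by the
#' sequential-backbone rule instead.
#'
#' @param resA,resB residue records from an `mc_structure`.
#' @param params a [rin_params()] object.
#' @return non-negative numeric weight.
#' @export
spatial_contact_weight <- function(resA, resB, params = rin_params()) {
  nc <- c(resA$n_conformers, resB$n_conformers)
  ok <- if (params$min_conformers_mode == "one") {
    any(nc >= params$min_conformers)
  } else {
    all(nc >= params$min_conformers)
  }
  if (!ok) return(0)
  aA <- resA$atoms[resA$atoms$altloc != "", , drop = FALSE]
  aB <- resB$atoms[resB$atoms$altloc != "", , drop = FALSE]
  if (nrow(aA) == 0 || nrow(aB) == 0) return(0)
  d2 <- pair_dist2(atom_xyz(aA), atom_xyz(aB))
  P <- sum(d2 <= params$contact_cutoff^2)
  if (P == 0) return(0)
  P / .size_norm(resA$n_unique_atoms, resB$n_unique_atoms, params)
}

# >= 2 distinct altloc labels among backbone atoms
.has_backbone_alt <- function(res) {
  bb <- res$atoms$is_backbone & res$atoms$altloc != ""
  length(unique(res$atoms$altloc[bb])) >= 2
}

# consecutive residues of one chain: adjacent in order and author numbers
# within 1 (insertion-coded residues share a number)
.seq_adjacent_pairs <- function(residues) {
  if (length(residues) < 2) return(integer(0))
  resno <- vapply(residues, function(r) r$resno, numeric(1))
  which(diff(resno) <= 1)
}

#' Sequential-backbone coupling edges along a chain
#'
#' Backbone alternate conformations of sequentially adjacent residues are
#' coupled through the peptide bond rather than through generic spatial
#' contact. This routine finds maximal runs of consecutive residues in which
#' every residue has at least two backbone conformers (backbone atoms N, CA,
#' C, O carrying non-blank altlocs); a run is extended residue by residue
#' while that condition holds. Within each run, every adjacent pair (i, i+1)
#' receives an edge of weight `B / (U_i + U_j)` where `B` counts backbone
#' altloc-atom pairs of the two residues within the contact cutoff.
#'
#' @param chain_residues list of residue records of one chain, ordered by
#'   sequence number.
#' @param params a [rin_params()] object.
#' @return data frame of edges (`i`, `j`, `weight`, `provenance =
#'   "sequential"`); zero-weight pairs are omitted.
#' @export
sequential_backbone_edges <- function(chain_residues, params = rin_params()) {
  edges <- empty_edges()
  n <- length(chain_residues)
  if (n < 2) return(edges)
  has_alt <- vapply(chain_residues, .has_backbone_alt, logical(1))
  adjacent <- logical(n - 1)
  adjacent[.seq_adjacent_pairs(chain_residues)] <- TRUE

  # maximal runs: consecutive stretches where each member has backbone
  # altlocs and neighbours are sequence-adjacent
  linked <- adjacent & has_alt[-n] & has_alt[-1]
  for (k in which(linked)) {
    a <- chain_residues[[k]]
    b <- chain_residues[[k + 1]]
    aA <- a$atoms[a$atoms$is_backbone & a$atoms$altloc != "", , drop = FALSE]
    aB <- b$atoms[b$atoms$is_backbone & b$atoms$altloc != "", , drop = FALSE]
    B <- sum(pair_dist2(atom_xyz(aA), atom_xyz(aB)) <=
               params$contact_cutoff^2)
    if (B > 0) {
      w <- B / .size_norm(a$n_unique_atoms, b$n_unique_atoms, params)
      edges <- rbind(edges, data.frame(i = a$key, j = b$key, weight = w,
                                       provenance = "sequential",
                                       stringsAsFactors = FALSE))
    }
  }
  edges
}

#' Build the residue interaction network of one structure
#'
#' Union of spatial altloc-contact edges over all non-sequence-adjacent
#' residue pairs and sequential-backbone edges along each chain. Zero-weight
#' edges are omitted; output is deterministic for a fixed input (edges stored
#' with the lower residue key first, sorted). A centroid-plus-radius bound is
#' used to skip residue pairs that cannot contain a contact; results are
#' identical to the unfiltered computation.
#'
#' @param structure an `mc_structure`.
#' @param params a [rin_params()] object.
#' @return An object of class `residue_rin`: list with `structure_id`,
#'   `nodes` (all residue keys) and `edges` (data frame `i`, `j`, `weight`,
#'   `provenance`).
#' @export
build_network <- function(structure, params = rin_params()) {
  stopifnot(inherits(structure, "mc_structure"))
  res <- structure$residues
  keys <- names(res)
  ord <- stats::setNames(seq_along(keys), keys)
  n <- length(res)

  chains <- vapply(res, function(r) r$chain, character(1))
  resno <- vapply(res, function(r) r$resno, numeric(1))
  nconf <- vapply(res, function(r) r$n_conformers, numeric(1))
  has_any_alt <- nconf >= 2 |
    vapply(res, function(r) any(r$atoms$altloc != ""), logical(1))

  spatial <- empty_edges()
  if (n >= 2) {
    bounds <- lapply(res, residue_bounds)
    centers <- do.call(rbind, lapply(bounds, function(b) b$center))
    radii <- vapply(bounds, function(b) b$radius, numeric(1))
    cutoff <- params$contact_cutoff
    rows <- list()
    for (a in seq_len(n - 1)) {
      if (!has_any_alt[a] && params$min_conformers_mode == "both") next
      for (b in (a + 1):n) {
        # sequence-adjacent pairs belong to the sequential rule
        if (chains[a] == chains[b] && b == a + 1 &&
            (resno[b] - resno[a]) <= 1) next
        dc <- sqrt(sum((centers[a, ] - centers[b, ])^2))
        if (dc - radii[a] - radii[b] > cutoff) next
        w <- spatial_contact_weight(res[[a]], res[[b]], params)
        if (w > 0) {
          rows[[length(rows) + 1]] <-
            data.frame(i = keys[a], j = keys[b], weight = w,
                       provenance = "spatial", stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) > 0) spatial <- do.call(rbind, rows)
  }

  seq_edges <- empty_edges()
  for (ch in unique(chains)) {
    seq_edges <- rbind(seq_edges,
                       sequential_backbone_edges(res[chains == ch], params))
  }

  edges <- canonicalize_edges(rbind(spatial, seq_edges), ord)
  structure(list(structure_id = structure$structure_id,
                 nodes = keys, edges = edges),
            class = "residue_rin")
}

#' @export
print.residue_rin <- function(x, ...) {
  cat("Residue interaction network", x$structure_id, "\n")
  cat("  nodes:", length(x$nodes), " edges:", nrow(x$edges),
      " total weight:", signif(sum(x$edges$weight), 5), "\n")
  invisible(x)
}
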