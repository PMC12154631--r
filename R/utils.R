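# Internal helpers shared across modules.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# 3-letter -> 1-letter code for the 20 standard amino acids plus
# selenomethionine (kept, as in qFit models of Met-substituted crystals).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

res_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste0(chain, ":", resno, icode)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical undirected edge table: endpoint with the lower order index
# first, rows sorted by (i, j).  `ord` maps node key -> integer rank.
canonicalize_edges <- function(edges, ord) {
  if (nrow(edges) == 0) return(edges[order(edges$i), , drop = FALSE])
  oi <- ord[edges$i]
  oj <- ord[edges$j]
  swap <- oi > oj
  tmp <- edges$i[swap]
  edges$i[swap] <- edges$j[swap]
  edges$j[swap] <- tmp
  o2 <- order(ord[edges$i], ord[edges$j])
  rownames(edges) <- NULL
  edges[o2, , drop = FALSE]
}

empty_edges <- function(provenance = TRUE) {
  e <- data.frame(i = character(), j = character(), weight = numeric(),
                  stringsAsFactors = FALSE)
  if (provenance) e$provenance <- character()
  e
}

# Minimum inter-atom distance prefilter bound: centroid distance minus the
# two bounding radii can never underestimate the true minimum distance.
residue_bounds <- function(res) {
  xyz <- as.matrix(res$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  r <- if (nrow(xyz) > 0) sqrt(max(rowSums(sweep(xyz, 2, ctr)^2))) else 0
  list(center = ctr, radius = r)
}

pair_dist2 <- function(a, b) {
  # squared distances between rows of two coordinate matrices
  outer(a[, 1], b[, 1], "-")^2 +
    outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
}

atom_xyz <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  m
}
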