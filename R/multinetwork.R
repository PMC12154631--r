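# Multinetwork stage: align per-structure networks onto common alignment
# columns, log-normalize, aggregate, and compare subsets.

.canonical_int_edges <- function(edges) {
  if (nrow(edges) == 0) {
    return(data.frame(i = integer(), j = integer(), weight = numeric()))
  }
  swap <- edges$i > edges$j
  tmp <- edges$i[swap]
  edges$i[swap] <- edges$j[swap]
  edges$j[swap] <- tmp
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Re-index a residue network onto alignment columns
#'
#' Replaces residue keys by 1-based alignment column indices through an
#' [build_residue_map()] result. Edges whose endpoints both map are retained
#' (including edges touching reference-gap columns, which keep a column key
#' but no reference number); edges with an unmapped endpoint are dropped and
#' counted.
#'
#' @param rin a `residue_rin`.
#' @param map an `alignment_map` for the same structure.
#' @return An object of class `aligned_rin`: list with `structure_id`,
#'   `edges` (data frame `i`, `j` integer columns, `weight`), `nodes`
#'   (columns occupied by the structure's residues) and `n_dropped`.
#' @export
align_rin <- function(rin, map) {
  stopifnot(inherits(rin, "residue_rin"), inherits(map, "alignment_map"))
  if (!identical(rin$structure_id, map$structure_id)) {
    stop("structure_id mismatch: network '", rin$structure_id,
         "' vs map '", map$structure_id, "'", call. = FALSE)
  }
  ci <- map$col_of_res[rin$edges$i]
  cj <- map$col_of_res[rin$edges$j]
  keep <- !is.na(ci) & !is.na(cj)
  edges <- data.frame(i = as.integer(ci[keep]), j = as.integer(cj[keep]),
                      weight = rin$edges$weight[keep])
  structure(list(structure_id = rin$structure_id,
                 edges = .canonical_int_edges(edges),
                 nodes = sort(unname(map$col_of_res[rin$nodes[
                   rin$nodes %in% names(map$col_of_res)]])),
                 n_dropped = sum(!keep),
                 norm = NULL),
            class = "aligned_rin")
}

#' Log-normalize an aligned network by its total edge weight
#'
#' Networks from high-resolution structures carry many more alternate
#' conformations and hence far larger total edge weight; to discourage
#' unbalanced contributions, each network is rescaled so that its total edge
#' weight `T` becomes `ln(1 + T)` (every edge multiplied by `ln(1 + T) / T`).
#' Networks with `T <= 1` are left unchanged (the scaling would inflate
#' them). The raw total and scale factor are recorded in `$norm`.
#'
#' @param rin an `aligned_rin`.
#' @param base logarithm base (default `exp(1)`).
#' @param offset offset inside the logarithm (default 1).
#' @return the rescaled `aligned_rin`.
#' @export
log_normalize <- function(rin, base = exp(1), offset = 1) {
  stopifnot(inherits(rin, "aligned_rin"))
  total <- sum(rin$edges$weight)
  scale <- if (total <= 1) 1 else log(offset + total, base = base) / total
  rin$edges$weight <- rin$edges$weight * scale
  rin$norm <- list(total_raw = total, scale = scale)
  rin
}

#' Assemble a multinetwork from aligned, normalized networks
#'
#' Joins per-structure networks (all on one alignment column space) with the
#' structure metadata table. Structures lacking a metadata row receive a stub
#' record with unknown fields (warning).
#'
#' @param rins list of `aligned_rin` objects (normalized).
#' @param metadata data frame from [read_metadata_table()], or `NULL`.
#' @param ref_of_col integer vector mapping columns to reference residue
#'   numbers (from any member's `alignment_map`), `NA` at reference gaps.
#' @return An object of class `multinetwork`: list with `networks` (named by
#'   structure_id), `metadata`, `ref_of_col` and `n_columns`.
#' @export
build_multinetwork <- function(rins, metadata = NULL, ref_of_col = NULL) {
  if (length(rins) == 0) stop("empty network list", call. = FALSE)
  stopifnot(all(vapply(rins, inherits, logical(1), "aligned_rin")))
  ids <- vapply(rins, function(r) r$structure_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate structure_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(rins) <- ids
  if (is.null(metadata)) {
    metadata <- data.frame(structure_id = character(),
                           protein_name = character(),
                           resolution = numeric(),
                           wpd_state = character(),
                           ligand_class = character(),
                           stringsAsFactors = FALSE)
  }
  missing <- setdiff(ids, metadata$structure_id)
  if (length(missing) > 0) {
    warning("no metadata for: ", paste(missing, collapse = ", "),
            " (stub records with unknown fields added)", call. = FALSE)
    stub <- data.frame(structure_id = missing,
                       protein_name = NA_character_,
                       resolution = NA_real_,
                       wpd_state = "unknown",
                       ligand_class = "other",
                       stringsAsFactors = FALSE)
    common <- intersect(names(metadata), names(stub))
    metadata <- rbind(metadata[, common, drop = FALSE],
                      stub[, common, drop = FALSE])
  }
  metadata <- metadata[metadata$structure_id %in% ids, , drop = FALSE]
  metadata <- metadata[match(ids, metadata$structure_id), , drop = FALSE]
  rownames(metadata) <- NULL
  n_columns <- max(c(1L, unlist(lapply(rins, function(r) r$nodes))),
                   length(ref_of_col))
  structure(list(networks = rins, metadata = metadata,
                 ref_of_col = ref_of_col %||% rep(NA_integer_, n_columns),
                 n_columns = as.integer(n_columns)),
            class = "multinetwork")
}

#' @export
print.multinetwork <- function(x, ...) {
  cat("Multinetwork:", length(x$networks), "structures over",
      x$n_columns, "alignment columns\n")
  invisible(x)
}

# Resolve a subset specification to structure IDs: NULL (all), a character
# vector of IDs, a logical vector over members, or a predicate function
# taking the metadata data frame and returning a logical vector.
.select_ids <- function(mn, subset) {
  ids <- names(mn$networks)
  sel <- if (is.null(subset)) {
    ids
  } else if (is.function(subset)) {
    keep <- subset(mn$metadata)
    if (!is.logical(keep) || length(keep) != length(ids)) {
      stop("subset predicate must return one logical per structure",
           call. = FALSE)
    }
    ids[which(keep)]
  } else if (is.logical(subset)) {
    ids[which(subset)]
  } else {
    bad <- setdiff(subset, ids)
    if (length(bad) > 0) {
      stop("unknown structure_id in subset: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    as.character(subset)
  }
  if (length(sel) == 0) {
    stop("subset '", deparse(substitute(subset)),
         "' selects no structures", call. = FALSE)
  }
  sel
}

#' Sum network over a subset of structures
#'
#' Per-edge sum of normalized edge weights over the selected structures,
#' optionally divided by the subset size (`per_structure_average`), which is
#' required when comparing subsets of unequal size.
#'
#' @param mn a `multinetwork`.
#' @param subset `NULL` (all structures), character IDs, a logical vector, or
#'   a predicate `function(metadata) -> logical`.
#' @param per_structure_average divide summed weights by the subset size.
#' @return An object of class `sum_network`: list with `edges` (`i`, `j`,
#'   `weight`), `nodes`, `n_structures`, `averaged` and `ref_of_col`.
#' @export
sum_network <- function(mn, subset = NULL, per_structure_average = FALSE) {
  stopifnot(inherits(mn, "multinetwork"))
  ids <- .select_ids(mn, subset)
  all_edges <- do.call(rbind, lapply(mn$networks[ids], function(r) r$edges))
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    edges <- data.frame(i = integer(), j = integer(), weight = numeric())
  } else {
    key <- paste(all_edges$i, all_edges$j)
    w <- tapply(all_edges$weight, key, sum)
    parts <- do.call(rbind, strsplit(names(w), " "))
    edges <- .canonical_int_edges(data.frame(
      i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
      weight = as.numeric(w)))
  }
  if (per_structure_average) edges$weight <- edges$weight / length(ids)
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$i, edges$j))),
                 n_structures = length(ids),
                 structure_ids = ids,
                 averaged = per_structure_average,
                 ref_of_col = mn$ref_of_col),
            class = "sum_network")
}

#' @export
print.sum_network <- function(x, ...) {
  cat("Sum network over", x$n_structures, "structures:",
      length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Trim a network to its highest-weight edges
#'
#' Retains the `ceiling(keep_fraction * n_edges)` highest-weight edges; all
#' edges tied with the threshold weight are retained (so the result may
#' exceed the nominal count). Nodes left without edges are dropped. The
#' fraction always refers to the network the trim was first applied to: the
#' result records its trim fraction, and re-trimming at the same fraction is
#' a no-op (idempotent).
#'
#' @param net a `sum_network` with at least one edge.
#' @param keep_fraction fraction of edges to keep, in (0, 1].
#' @return trimmed `sum_network`.
#' @export
trim_top_fraction <- function(net, keep_fraction = 0.05) {
  stopifnot(inherits(net, "sum_network"),
            keep_fraction > 0, keep_fraction <= 1)
  if (!is.null(net$trim_fraction) && net$trim_fraction == keep_fraction) {
    return(net)
  }
  n <- nrow(net$edges)
  if (n == 0) stop("cannot trim an empty network", call. = FALSE)
  k <- ceiling(keep_fraction * n)
  thr <- sort(net$edges$weight, decreasing = TRUE)[k]
  keep <- net$edges$weight >= thr
  net$edges <- net$edges[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  net$nodes <- sort(unique(c(net$edges$i, net$edges$j)))
  net$trim_fraction <- keep_fraction
  net
}

#' Weighted degree of every node
#'
#' Degree of a node is the sum of the weights of its incident edges.
#'
#' @param net a `sum_network` (or `residue_rin`).
#' @param nodes optional vector of nodes to report (absent nodes get 0);
#'   defaults to the network's nodes.
#' @return named numeric vector of degrees.
#' @export
weighted_degree <- function(net, nodes = NULL) {
  edges <- net$edges
  nodes <- nodes %||% net$nodes
  deg <- stats::setNames(numeric(length(nodes)), as.character(nodes))
  if (nrow(edges) > 0) {
    tab <- tapply(c(edges$weight, edges$weight),
                  c(as.character(edges$i), as.character(edges$j)), sum)
    hit <- intersect(names(tab), names(deg))
    deg[hit] <- tab[hit]
  }
  deg
}

#' Per-residue difference in weighted degree between two subsets
#'
#' Computes `degree_A - degree_B` per alignment column on untrimmed,
#' per-structure-averaged subset sum networks, reported against reference
#' residue numbering (columns without a reference number carry `NA` there).
#' The sign convention is first-named subset minus second. Antisymmetric
#' under subset swap.
#'
#' @param mn a `multinetwork`.
#' @param subset_a,subset_b subset specifications (see [sum_network()]).
#' @param label_a,label_b labels recorded on the profile.
#' @return An object of class `delta_degree`: data frame with `column`,
#'   `ref_resno` and `delta`, with subset labels and sizes as attributes.
#' @export
delta_degree <- function(mn, subset_a, subset_b,
                         label_a = "A", label_b = "B") {
  stopifnot(inherits(mn, "multinetwork"))
  net_a <- sum_network(mn, subset_a, per_structure_average = TRUE)
  net_b <- sum_network(mn, subset_b, per_structure_average = TRUE)
  cols <- seq_len(mn$n_columns)
  deg_a <- weighted_degree(net_a, nodes = cols)
  deg_b <- weighted_degree(net_b, nodes = cols)
  out <- data.frame(column = cols,
                    ref_resno = mn$ref_of_col[cols],
                    delta = unname(deg_a - deg_b))
  attr(out, "label_a") <- label_a
  attr(out, "label_b") <- label_b
  attr(out, "n_a") <- net_a$n_structures
  attr(out, "n_b") <- net_b$n_structures
  class(out) <- c("delta_degree", "data.frame")
  out
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Random-half negative control for degree differences
#'
#' Splits the structures uniformly at random into two complementary halves
#' (sizes `floor(n/2)` and `ceiling(n/2)`), computes the per-residue degree
#' difference, and averages element-wise over `n_samples` splits. A
#' featureless (near-zero) averaged profile indicates that subset contrasts
#' are not artifacts of arbitrary partitioning. Exactly zero when all member
#' networks are identical; bit-reproducible for a fixed seed.
#'
#' @param mn a `multinetwork` with >= 2 structures.
#' @param n_samples number of random splits (default 70).
#' @param seed integer seed (required for reproducibility).
#' @return a `delta_degree` data frame (mean profile), with `n_samples`
#'   recorded as an attribute.
#' @export
random_half_control <- function(mn, n_samples = 70, seed) {
  stopifnot(inherits(mn, "multinetwork"), length(mn$networks) >= 2)
  ids <- names(mn$networks)
  n <- length(ids)
  half <- floor(n / 2)
  acc <- NULL
  .with_seed(seed, {
    for (s in seq_len(n_samples)) {
      a <- sample(ids, half)
      d <- delta_degree(mn, a, setdiff(ids, a),
                        label_a = "half1", label_b = "half2")
      acc <- if (is.null(acc)) d$delta else acc + d$delta
    }
  })
  cols <- seq_len(mn$n_columns)
  out <- data.frame(column = cols, ref_resno = mn$ref_of_col[cols],
                    delta = acc / n_samples)
  attr(out, "label_a") <- "random half"
  attr(out, "label_b") <- "complement"
  attr(out, "n_samples") <- n_samples
  class(out) <- c("delta_degree", "data.frame")
  out
}

#' One-tailed Mann-Whitney U test on resolution distributions
#'
#' Used to check that two structure subsets have comparable resolution
#' distributions before interpreting their degree difference (resolution
#' drives the number of modeled alternate conformations). `U = #\{a > b\} +
#' 0.5 #\{a = b\}`; for `alternative = "less"` the p-value is
#' `P(U_perm <= U_obs)` under random reassignment of the pooled values. The
#' p-value is computed by exhaustive enumeration of all group assignments
#' when `choose(nA+nB, nA) <= exact_limit` (exact even under ties), and by
#' the normal approximation with tie correction otherwise.
#'
#' @param res_a,res_b numeric vectors of resolutions (Angstrom).
#' @param alternative `"less"` (distribution A shifted to lower values) or
#'   `"greater"`.
#' @param exact_limit maximum number of assignments to enumerate.
#' @return list with `U`, `p_value` and `method`.
#' @export
resolution_balance_test <- function(res_a, res_b,
                                    alternative = c("less", "greater"),
                                    exact_limit = 20000) {
  alternative <- match.arg(alternative)
  if (length(res_a) == 0 || length(res_b) == 0) {
    stop("both resolution sets must be non-empty", call. = FALSE)
  }
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U <- u_stat(res_a, res_b)
  na <- length(res_a)
  pooled <- c(res_a, res_b)
  n <- length(pooled)
  if (choose(n, na) <= exact_limit) {
    idx <- utils::combn(n, na)
    us <- apply(idx, 2, function(k) u_stat(pooled[k], pooled[-k]))
    p <- if (alternative == "less") mean(us <= U) else mean(us >= U)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(stats::wilcox.test(
      res_a, res_b, alternative = alternative, exact = FALSE,
      correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method)
}
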