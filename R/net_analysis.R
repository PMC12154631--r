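# Community structure of sum networks and colocalization of the network
# with residue sets of interest.

#' Girvan-Newman community detection at the modularity plateau
#'
#' Iteratively removes the edge of highest betweenness and records the
#' partition and weighted modularity each time the number of connected
#' components increases. Edge weights are treated as connection strengths:
#' betweenness is computed with distances `1/weight` (stronger edges are
#' shorter), while modularity uses the weights themselves. The chosen
#' partition is the first level whose modularity is within `eps` of the
#' running maximum and whose gain over the next level is below `eps` (the
#' modularity plateau). Betweenness ties are broken by canonical edge order.
#'
#' @param net a `sum_network` (or `residue_rin`) with >= 1 node.
#' @param eps plateau tolerance (default 0.005).
#' @param weighted use edge weights (default `TRUE`); unweighted mode treats
#'   every edge equally.
#' @return An object of class `community_partition`: list with `membership`
#'   (named integer), `modularity`, `n_communities`, `level`, and `trace`
#'   (data frame `level`, `n_communities`, `modularity`).
#' @export
girvan_newman <- function(net, eps = 0.005, weighted = TRUE) {
  edges <- net$edges
  nodes <- as.character(net$nodes)
  if (length(nodes) == 0) stop("empty graph", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j),
               weight = edges$weight),
    directed = FALSE, vertices = nodes)
  gw <- g
  full_w <- igraph::E(g)$weight

  comp <- igraph::components(gw)
  memberships <- list(comp$membership)
  mods <- igraph::modularity(g, comp$membership, weights = full_w)
  ncomm <- comp$no
  last_n <- comp$no

  while (igraph::ecount(gw) > 0) {
    ew <- igraph::E(gw)$weight
    eb <- igraph::edge_betweenness(gw,
                                   weights = if (weighted) 1 / ew else NULL)
    gw <- igraph::delete_edges(gw, which.max(eb))
    comp <- igraph::components(gw)
    if (comp$no > last_n) {
      last_n <- comp$no
      memberships[[length(memberships) + 1]] <- comp$membership
      mods <- c(mods, igraph::modularity(g, comp$membership,
                                         weights = full_w))
      ncomm <- c(ncomm, comp$no)
    }
  }

  L <- length(mods)
  level <- L
  runmax <- cummax(mods)
  for (l in seq_len(L)) {
    flat <- l == L || (mods[l + 1] - mods[l]) < eps
    if (mods[l] >= runmax[l] - eps && flat) {
      level <- l
      break
    }
  }
  structure(list(
    membership = memberships[[level]],
    modularity = mods[level],
    n_communities = ncomm[level],
    level = level,
    trace = data.frame(level = seq_len(L), n_communities = ncomm,
                       modularity = mods)
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities, modularity",
      signif(x$modularity, 4), "\n")
  invisible(x)
}

#' Count nearby network residues for every residue of a structure
#'
#' For each residue of a representative structure, counts how many residues
#' of a given network residue set (reference numbering) have at least one
#' heavy-atom pair within the cutoff. A residue that is itself a network node
#' does not count itself.
#'
#' @param structure a representative `mc_structure`.
#' @param network_resnos integer vector of network residues (reference
#'   numbering).
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @param map optional `alignment_map` translating the structure's residues
#'   to reference numbering; by default the author residue numbers are used
#'   (appropriate when the representative structure is the reference).
#' @return named integer vector: reference residue number -> count (residues
#'   without a reference number are skipped).
#' @export
nearby_network_count <- function(structure, network_resnos, cutoff = 4.0,
                                 map = NULL) {
  stopifnot(inherits(structure, "mc_structure"))
  res <- structure$residues
  refno <- if (is.null(map)) {
    vapply(res, function(r) as.integer(r$resno), integer(1))
  } else {
    cols <- map$col_of_res[names(res)]
    as.integer(map$ref_of_col[cols])
  }
  keep <- !is.na(refno)
  res <- res[keep]
  refno <- refno[keep]
  net_idx <- which(refno %in% network_resnos)

  bounds <- lapply(res, residue_bounds)
  centers <- do.call(rbind, lapply(bounds, function(b) b$center))
  radii <- vapply(bounds, function(b) b$radius, numeric(1))
  xyz <- lapply(res, function(r) atom_xyz(r$atoms))

  counts <- integer(length(res))
  for (a in seq_along(res)) {
    for (b in net_idx) {
      if (refno[b] == refno[a]) next  # self-exclusion
      dc <- sqrt(sum((centers[a, ] - centers[b, ])^2))
      if (dc - radii[a] - radii[b] > cutoff) next
      if (min(pair_dist2(xyz[[a]], xyz[[b]])) <= cutoff^2) {
        counts[a] <- counts[a] + 1L
      }
    }
  }
  stats::setNames(counts, refno)
}

#' Colocalization of the network with a residue set of interest
#'
#' Compares the nearby-network-residue counts of a set of interest against
#' size-matched random residue sets drawn (without replacement, per draw)
#' from all counted residues, with a two-sample Kolmogorov-Smirnov test.
#' In the default `"pooled"` mode the random draws are pooled into one
#' reference sample; `"per_draw"` runs one KS test per draw and reports the
#' median p-value. Also reports the Jaccard ratio `|network and set| /
#' |network or set|` when the network node set is supplied.
#'
#' @param counts named numeric vector from [nearby_network_count()].
#' @param set_of_interest residue numbers of the set of interest (must be a
#'   subset of `names(counts)`).
#' @param network_resnos optional network residue set for the Jaccard ratio.
#' @param n_random number of random draws (default 100).
#' @param seed integer seed.
#' @param mode `"pooled"` or `"per_draw"`.
#' @return An object of class `colocalization_result`: list with
#'   `counts_set`, `counts_random`, `ks_statistic`, `p_value`, `jaccard`,
#'   `n_random` and `mode`.
#' @export
colocalization_test <- function(counts, set_of_interest,
                                network_resnos = NULL, n_random = 100,
                                seed = 1, mode = c("pooled", "per_draw")) {
  mode <- match.arg(mode)
  set_of_interest <- as.character(set_of_interest)
  if (length(set_of_interest) == 0) {
    stop("set of interest is empty", call. = FALSE)
  }
  missing <- setdiff(set_of_interest, names(counts))
  if (length(missing) > 0) {
    stop("set of interest contains residues without counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- unname(counts[set_of_interest])
  size <- length(set_of_interest)
  universe <- names(counts)

  res <- .with_seed(seed, {
    draws <- lapply(seq_len(n_random), function(k) {
      unname(counts[sample(universe, size)])
    })
    if (mode == "pooled") {
      pooled <- unlist(draws)
      # the asymptotic two-sample KS p is conservative at typical set sizes;
      # use the exact distribution whenever it is affordable
      exact <- length(x) * length(pooled) <= 2e6
      kt <- suppressWarnings(stats::ks.test(x, pooled, exact = exact))
      list(stat = unname(kt$statistic), p = kt$p.value, random = pooled)
    } else {
      kts <- lapply(draws, function(y) {
        suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      })
      list(stat = mean(vapply(kts, function(k) unname(k$statistic),
                              numeric(1))),
           p = stats::median(vapply(kts, function(k) k$p.value, numeric(1))),
           random = unlist(draws))
    }
  })

  jaccard <- NA_real_
  if (!is.null(network_resnos)) {
    a <- unique(as.character(network_resnos))
    b <- unique(set_of_interest)
    jaccard <- length(intersect(a, b)) / length(union(a, b))
  }
  structure(list(counts_set = x, counts_random = res$random,
                 ks_statistic = res$stat, p_value = res$p,
                 jaccard = jaccard, n_random = n_random, mode = mode),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat("Colocalization: KS D =", signif(x$ks_statistic, 4),
      " p =", signif(x$p_value, 4),
      if (!is.na(x$jaccard)) paste(" Jaccard =", signif(x$jaccard, 4)), "\n")
  invisible(x)
}

#' Fraction of functionally influential mutations per nearby-count bin
#'
#' Bins curated mutations by the nearby-network-residue count of their
#' residue and reports the fraction that were functionally influential per
#' bin. Bins are left-inclusive, right-exclusive, except the last bin which
#' is closed on both sides. Empty bins are reported as `NA`, not 0.
#'
#' @param mutations data frame with columns `resno` (reference residue
#'   number) and `influential` (logical).
#' @param counts named numeric vector from [nearby_network_count()]; every
#'   mutation residue must have a count.
#' @param bin_edges increasing numeric vector of bin boundaries.
#' @return data frame with `bin_lo`, `bin_hi`, `n`, `n_influential`,
#'   `fraction`.
#' @export
mutation_bin_analysis <- function(mutations, counts, bin_edges) {
  stopifnot(is.data.frame(mutations),
            all(c("resno", "influential") %in% names(mutations)),
            length(bin_edges) >= 2, !is.unsorted(bin_edges))
  key <- as.character(mutations$resno)
  missing <- setdiff(key, names(counts))
  if (length(missing) > 0) {
    stop("mutation residue(s) without a count: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- unname(counts[key])
  out_of_range <- x < bin_edges[1] | x > bin_edges[length(bin_edges)]
  if (any(out_of_range)) {
    warning(sum(out_of_range), " mutation(s) outside the bin range dropped",
            call. = FALSE)
    x <- x[!out_of_range]
    mutations <- mutations[!out_of_range, , drop = FALSE]
  }
  bin <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  k <- length(bin_edges) - 1
  n <- tabulate(bin, nbins = k)
  n_infl <- vapply(seq_len(k), function(b) {
    sum(mutations$influential[bin == b])
  }, numeric(1))
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1],
             n = n, n_influential = n_infl,
             fraction = ifelse(n > 0, n_infl / n, NA_real_))
}

#' Weighted degree versus sequence conservation
#'
#' Pairs per-residue network degree with per-residue sequence conservation,
#' fits an ordinary least-squares line and reports R-squared. The returned
#' table is sorted by descending residual, so residues with high degree
#' relative to their conservation come first (candidates for mutagenesis).
#'
#' @param degrees named numeric vector (reference residue number -> degree).
#' @param conservation named numeric vector (reference residue number ->
#'   conservation fraction in `[0, 1]`).
#' @return list with `table` (data frame `ref_resno`, `degree`,
#'   `conservation`, `fitted`, `residual`), `slope`, `intercept`,
#'   `r_squared`, `slope_se` and `n`.
#' @export
degree_vs_conservation <- function(degrees, conservation) {
  shared <- intersect(names(degrees), names(conservation))
  if (length(shared) < 3) {
    stop("need >= 3 residues with both degree and conservation values",
         call. = FALSE)
  }
  d <- unname(degrees[shared])
  cons <- unname(conservation[shared])
  if (stats::sd(cons) == 0) {
    warning("conservation is constant; linear fit is degenerate",
            call. = FALSE)
    tab <- data.frame(ref_resno = shared, degree = d, conservation = cons,
                      fitted = mean(d), residual = d - mean(d))
    tab <- tab[order(-tab$residual), ]
    rownames(tab) <- NULL
    return(list(table = tab, slope = NA_real_, intercept = mean(d),
                r_squared = 0, slope_se = NA_real_, n = length(shared)))
  }
  fit <- stats::lm(d ~ cons)
  sm <- summary(fit)
  tab <- data.frame(ref_resno = shared, degree = d, conservation = cons,
                    fitted = unname(stats::fitted(fit)),
                    residual = unname(stats::resid(fit)))
  tab <- tab[order(-tab$residual), ]
  rownames(tab) <- NULL
  list(table = tab,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       slope_se = sm$coefficients[2, 2],
       n = length(shared))
}
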