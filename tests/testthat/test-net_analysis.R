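test_that("girvan-newman splits two bridged cliques into the cliques", {
  net <- barbell(5, 5)
  cp <- girvan_newman(net)
  expect_equal(cp$n_communities, 2)
  expect_true(same_partition(
    cp$membership,
    stats::setNames(rep(1:2, each = 5), as.character(1:10))))
  # agrees with exhaustive bipartition search
  best <- oracle_best_bipartition(net$edges, net$nodes)
  expect_true(same_partition(cp$membership, best$membership))
  expect_equal(cp$modularity, best$q, tolerance = 1e-9)
  expect_gte(cp$modularity, -0.5)
  expect_lte(cp$modularity, 1)
})

test_that("single-edge and degenerate graphs stay in one community", {
  single <- mk_sum_network(1, 2, 1)
  cp <- girvan_newman(single)
  expect_equal(cp$n_communities, 1)
  expect_error(girvan_newman(mk_sum_network(integer(), integer(),
                                            numeric())),
               "empty")
})

test_that("plateau partitions match exhaustive modularity search (<= 8 nodes)", {
  fixtures <- list(
    barbell(3, 3),
    barbell(4, 4),
    barbell(3, 4, bridge_w = 0.5),
    # two weighted triangles with a weak bridge
    mk_sum_network(c(1, 1, 2, 4, 4, 5, 3),
                   c(2, 3, 3, 5, 6, 6, 4),
                   c(3, 2.5, 3, 2, 2.2, 2.8, 0.3))
  )
  for (net in fixtures) {
    cp <- girvan_newman(net)
    best <- oracle_best_partition(net$edges, net$nodes)
    expect_true(same_partition(cp$membership, best$membership))
    expect_equal(cp$modularity, best$q, tolerance = 1e-9)
  }
})

test_that("removing the bridge beforehand never merges the communities", {
  for (w in c(0.5, 1, 2)) {
    net <- barbell(4, 5, bridge_w = w)
    cp_with <- girvan_newman(net)
    cut <- net
    keep <- !(cut$edges$i == 4 & cut$edges$j == 5)
    cut$edges <- cut$edges[keep, ]
    cp_cut <- girvan_newman(cut)
    # the clique split survives
    left <- as.character(1:4)
    right <- as.character(5:9)
    expect_length(unique(cp_cut$membership[left]), 1)
    expect_length(unique(cp_cut$membership[right]), 1)
    expect_false(cp_cut$membership[left][1] == cp_cut$membership[right][1])
    expect_gte(cp_cut$n_communities, cp_with$n_communities)
  }
})

test_that("nearby-network counts follow brute-force distances", {
  st <- mk_structure(list(
    mk_res(1, c("CA", "CB"), c("", ""), c(0, 0, 0, 1, 0, 0)),
    mk_res(2, c("CA", "CB"), c("", ""), c(3.5, 0, 0, 4.5, 0, 0)),
    mk_res(3, c("CA"), c(""), c(50, 0, 0))
  ))
  # empty network: all counts zero
  expect_equal(unname(nearby_network_count(st, integer())), c(0L, 0L, 0L))

  counts <- nearby_network_count(st, c(2L))
  expect_equal(counts, c(`1` = 1L, `2` = 0L, `3` = 0L))

  # a residue that is itself a network node counts only its neighbours
  counts2 <- nearby_network_count(st, c(1L, 2L, 3L))
  expect_equal(counts2, c(`1` = 1L, `2` = 1L, `3` = 0L))

  # brute-force verification on a generated fixture
  spec <- fixture_spec(n_residues = 12,
                       planted_contacts = data.frame(i = 2L, j = 9L),
                       seed = 31)
  gen <- generate_structure(spec)$structure
  net_res <- c(2L, 9L, 5L)
  got <- nearby_network_count(gen, net_res)
  for (k in seq_along(gen$residues)) {
    r <- gen$residues[[k]]
    expected <- 0L
    for (n in net_res) {
      if (n == r$resno) next
      other <- gen$residues[[paste0("A:", n)]]
      dmin <- Inf
      for (p in seq_len(nrow(r$atoms))) {
        for (q in seq_len(nrow(other$atoms))) {
          dmin <- min(dmin, adist1(
            c(r$atoms$x[p], r$atoms$y[p], r$atoms$z[p]),
            c(other$atoms$x[q], other$atoms$y[q], other$atoms$z[q])))
        }
      }
      if (dmin <= 4) expected <- expected + 1L
    }
    expect_equal(unname(got[k]), expected)
  }
})

test_that("colocalization handles identity limits and planted shifts", {
  set.seed(42)
  counts <- stats::setNames(rnorm(120, 5, 2), 1:120)

  # set of interest = whole universe: random sets are the universe too
  r_all <- colocalization_test(counts, names(counts), n_random = 20,
                               seed = 9)
  expect_equal(r_all$ks_statistic, 0)

  # Jaccard identities and symmetry
  r_net <- colocalization_test(counts, as.character(1:30),
                               network_resnos = 1:30, n_random = 10,
                               seed = 9)
  expect_equal(r_net$jaccard, 1)
  r_disj <- colocalization_test(counts, as.character(1:30),
                                network_resnos = 31:60, n_random = 10,
                                seed = 9)
  expect_equal(r_disj$jaccard, 0)
  a <- colocalization_test(counts, as.character(10:40),
                           network_resnos = 25:55, n_random = 10, seed = 9)
  b <- colocalization_test(counts, as.character(25:55),
                           network_resnos = 10:40, n_random = 10, seed = 9)
  expect_equal(a$jaccard, b$jaccard)

  # a shifted set of interest is detected
  shifted <- counts
  soi <- as.character(1:50)
  shifted[soi] <- shifted[soi] + 2
  r_shift <- colocalization_test(shifted, soi, n_random = 1000, seed = 9)
  expect_lt(r_shift$p_value, 0.05)

  # reproducibility under a fixed seed
  r_a <- colocalization_test(counts, as.character(1:30), n_random = 50,
                             seed = 4)
  r_b <- colocalization_test(counts, as.character(1:30), n_random = 50,
                             seed = 4)
  expect_identical(r_a$p_value, r_b$p_value)

  expect_error(colocalization_test(counts, character()), "empty")
  expect_error(colocalization_test(counts, "999"), "without counts")
})

test_that("mutation bins report fractions and leave empty bins undefined", {
  counts <- stats::setNames(c(0, 1, 2, 5, 7, 11), 1:6)
  muts <- data.frame(resno = c(1, 2, 3, 4, 5, 6),
                     influential = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  bins <- mutation_bin_analysis(muts, counts, bin_edges = c(0, 3, 6, 9, 12))
  expect_equal(bins$n, c(3, 1, 1, 1))
  expect_equal(bins$fraction, c(1 / 3, 1, 1, 1))

  all_infl <- mutation_bin_analysis(
    data.frame(resno = 1:3, influential = TRUE), counts, c(0, 3))
  expect_equal(all_infl$fraction, 1)

  with_gap <- mutation_bin_analysis(
    data.frame(resno = c(1, 6), influential = c(TRUE, FALSE)),
    counts, c(0, 3, 6, 12))
  expect_true(is.na(with_gap$fraction[2]))
  expect_equal(with_gap$n[2], 0)

  expect_error(mutation_bin_analysis(
    data.frame(resno = 99, influential = TRUE), counts, c(0, 3)),
    "without a count")
})

test_that("degree-conservation fit recovers planted slopes", {
  # collinear points: R^2 = 1
  cons <- stats::setNames(seq(0.1, 0.9, length.out = 10), 1:10)
  deg <- 3 * cons + 1
  fit <- suppressWarnings(degree_vs_conservation(deg, cons))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 3)

  # constant conservation: degenerate fit, R^2 reported 0
  flat <- stats::setNames(rep(0.5, 10), 1:10)
  expect_warning(fd <- degree_vs_conservation(deg, flat), "degenerate")
  expect_equal(fd$r_squared, 0)
  expect_true(is.na(fd$slope))

  # slope recovery on noisy synthetic data, within 3 standard errors
  set.seed(99)
  cons_n <- stats::setNames(runif(200), 1:200)
  deg_n <- 2 * cons_n + rnorm(200, 0, 0.4)
  fr <- degree_vs_conservation(deg_n, cons_n)
  expect_lt(abs(fr$slope - 2), 3 * fr$slope_se)
  # residual ordering surfaces high-degree-given-conservation residues
  expect_equal(fr$table$residual, sort(fr$table$residual, decreasing = TRUE))

  expect_error(degree_vs_conservation(deg[1:2], cons[1:2]), ">= 3")
})
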