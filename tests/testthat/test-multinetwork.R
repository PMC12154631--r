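meta_for <- function(ids) {
  data.frame(structure_id = ids, protein_name = "SYN",
             resolution = 1.5, wpd_state = "unknown",
             ligand_class = "other", stringsAsFactors = FALSE)
}

mn_of <- function(rins, ref_of_col = NULL) {
  build_multinetwork(rins, meta_for(vapply(rins, function(r) r$structure_id,
                                           character(1))),
                     ref_of_col = ref_of_col)
}

test_that("aligning a network re-keys edges and drops unmapped endpoints", {
  spec <- fixture_spec(n_residues = 6,
                       planted_contacts = data.frame(i = 2L, j = 5L),
                       seed = 2)
  st <- generate_structure(spec)$structure
  rin <- build_network(st)

  fa <- withr::local_tempfile(fileext = ".fasta")
  aa <- vapply(st$residues, function(r) r$aa1, character(1))
  writeLines(c(">syn01", paste(aa, collapse = ""),
               ">ref", paste(aa, collapse = "")), fa)
  aln <- read_alignment(fa)
  map <- build_residue_map(aln, "syn01", st, "ref")

  arin <- align_rin(rin, map)
  expect_s3_class(arin, "aligned_rin")
  expect_equal(arin$edges$i, 2L)
  expect_equal(arin$edges$j, 5L)
  expect_equal(arin$edges$weight, rin$edges$weight)
  expect_equal(arin$n_dropped, 0)

  # a partial map loses the edge and reports it
  partial <- map
  partial$col_of_res <- partial$col_of_res[-5]
  arin2 <- align_rin(rin, partial)
  expect_equal(nrow(arin2$edges), 0)
  expect_equal(arin2$n_dropped, 1)

  wrong <- map
  wrong$structure_id <- "other"
  expect_error(align_rin(rin, wrong), "structure_id mismatch")
})

test_that("log normalization rescales totals above 1 to ln(1 + T)", {
  # empty network untouched
  e0 <- log_normalize(mk_aligned("x", integer(), integer(), numeric()))
  expect_equal(nrow(e0$edges), 0)
  expect_equal(e0$norm$scale, 1)

  # total <= 1 untouched
  small <- log_normalize(mk_aligned("x", 1, 3, 1))
  expect_equal(small$edges$weight, 1)

  # two edges of weight e - 1 each: total becomes ln(2e - 1)
  two <- log_normalize(mk_aligned("x", c(1, 2), c(3, 4),
                                  c(exp(1) - 1, exp(1) - 1)))
  expect_equal(sum(two$edges$weight), log(2 * exp(1) - 1), tolerance = 1e-9)
  expect_equal(two$edges$weight,
               rep(log(2 * exp(1) - 1) / 2, 2), tolerance = 1e-9)

  # normalized total equals ln(1 + T) regardless of edge order
  w <- c(0.4, 1.3, 2.7, 0.1)
  a <- log_normalize(mk_aligned("x", 1:4, 6:9, w))
  b <- log_normalize(mk_aligned("x", c(4, 2, 1, 3), c(9, 7, 6, 8), rev(w)[c(1, 3, 4, 2)]))
  expect_equal(sum(a$edges$weight), log(1 + sum(w)), tolerance = 1e-9)
  expect_equal(sum(a$edges$weight), sum(b$edges$weight), tolerance = 1e-9)
})

test_that("multinetwork assembly joins metadata and rejects duplicates", {
  rins <- list(mk_aligned("a", 1, 3, 1), mk_aligned("b", 1, 3, 2),
               mk_aligned("c", 2, 4, 1))
  mn <- mn_of(rins)
  expect_length(mn$networks, 3)
  expect_equal(mn$metadata$structure_id, c("a", "b", "c"))

  expect_warning(
    mn2 <- build_multinetwork(rins, meta_for(c("a", "b"))),
    "no metadata for: c")
  expect_equal(mn2$metadata$wpd_state[3], "unknown")

  expect_error(build_multinetwork(list()), "empty")
  expect_error(mn_of(list(mk_aligned("a", 1, 3, 1),
                          mk_aligned("a", 1, 3, 2))),
               "duplicate")
})

test_that("sum networks add per edge and average per structure", {
  r1 <- mk_aligned("a", c(1, 2), c(3, 4), c(1, 2))
  r2 <- mk_aligned("b", c(1, 5), c(3, 8), c(3, 4))
  mn <- mn_of(list(r1, r2))

  # subset of one equals that structure's network
  s1 <- sum_network(mn, "a")
  expect_equal(s1$edges[, c("i", "j", "weight")], r1$edges,
               ignore_attr = TRUE)

  # shared edge adds, disjoint edges carry through
  s <- sum_network(mn)
  expect_equal(s$edges$weight[s$edges$i == 1 & s$edges$j == 3], 4)
  expect_equal(nrow(s$edges), 3)

  # two identical structures with averaging reproduce one of them
  mn_id <- mn_of(list(r1, mk_aligned("b", c(1, 2), c(3, 4), c(1, 2))))
  avg <- sum_network(mn_id, per_structure_average = TRUE)
  expect_equal(avg$edges[, c("i", "j", "weight")], r1$edges,
               ignore_attr = TRUE)

  # additivity over disjoint subsets (averaging off)
  r3 <- mk_aligned("c", c(2, 6), c(4, 9), c(5, 0.5))
  mn3 <- mn_of(list(r1, r2, r3))
  sa <- sum_network(mn3, c("a", "b"))
  sb <- sum_network(mn3, "c")
  sall <- sum_network(mn3)
  key <- function(net) stats::setNames(net$edges$weight,
                                       paste(net$edges$i, net$edges$j))
  combined <- key(sall)
  parts <- c(key(sa), key(sb))
  agg <- tapply(parts, names(parts), sum)
  expect_equal(as.numeric(combined[names(agg)]), as.numeric(agg))

  expect_error(sum_network(mn, character(0)), "selects no structures")
  expect_error(sum_network(mn, "nope"), "unknown structure_id")
  # predicate form
  s_pred <- sum_network(mn, function(md) md$structure_id == "b")
  expect_equal(s_pred$edges$weight, r2$edges$weight)
})

test_that("trimming keeps the top fraction with ties and is idempotent", {
  set.seed(1)
  w <- sample(seq(0.01, 1, length.out = 100))
  net <- mk_sum_network(rep(1:10, 10), rep(11:20, each = 10), w)
  expect_equal(nrow(trim_top_fraction(net, 1)$edges), 100)

  t5 <- trim_top_fraction(net, 0.05)
  expect_equal(nrow(t5$edges), 5)
  expect_setequal(t5$edges$weight, sort(w, decreasing = TRUE)[1:5])
  # isolated nodes are dropped
  expect_equal(sort(t5$nodes), sort(unique(c(t5$edges$i, t5$edges$j))))

  # idempotence at the same fraction
  expect_equal(trim_top_fraction(t5, 0.05)$edges, t5$edges)

  # all-tied weights are all retained
  tied <- mk_sum_network(rep(1, 10), 2:11, rep(0.7, 10))
  expect_equal(nrow(trim_top_fraction(tied, 0.05)$edges), 10)

  empty <- mk_sum_network(integer(), integer(), numeric())
  expect_error(trim_top_fraction(empty, 0.05), "empty")
})

test_that("weighted degree sums incident edge weights", {
  tri <- mk_sum_network(c(1, 2, 1), c(2, 3, 3), c(1, 2, 3))
  deg <- weighted_degree(tri)
  expect_equal(deg, c(`1` = 4, `2` = 3, `3` = 5))

  star <- mk_sum_network(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_equal(unname(weighted_degree(star, nodes = c(0, 1, 2, 3, 9))),
               c(3, 1, 1, 1, 0))

  empty <- mk_sum_network(integer(), integer(), numeric())
  expect_equal(unname(weighted_degree(empty, nodes = 1:3)), c(0, 0, 0))
})

test_that("degree differences are antisymmetric and subset-aware", {
  r1 <- mk_aligned("a", c(1, 2), c(3, 4), c(1, 2))
  r2 <- mk_aligned("b", c(1, 5), c(3, 8), c(3, 4))
  r3 <- mk_aligned("c", integer(), integer(), numeric())
  mn <- mn_of(list(r1, r2, r3), ref_of_col = c(101:108))

  d_same <- delta_degree(mn, c("a", "b"), c("a", "b"))
  expect_true(all(d_same$delta == 0))

  d_ab <- delta_degree(mn, "a", "b")
  d_ba <- delta_degree(mn, "b", "a")
  expect_identical(d_ab$delta, -d_ba$delta)
  expect_equal(d_ab$ref_resno, 101:108)

  # single-edge subset against an empty-network subset: A's own degrees
  d <- delta_degree(mn, "a", "c")
  expect_equal(d$delta[1:4], c(1, 2, 1, 2))
  expect_error(delta_degree(mn, character(0), "b"), "selects no structures")
})

test_that("random-half control vanishes for identical members and is seeded", {
  same <- lapply(c("a", "b", "c", "d"), function(id) {
    mk_aligned(id, c(1, 2), c(3, 4), c(1, 2))
  })
  mn <- mn_of(same)
  ctrl <- random_half_control(mn, n_samples = 70, seed = 7)
  expect_true(all(ctrl$delta == 0))

  varied <- lapply(1:20, function(k) {
    mk_aligned(paste0("s", k), c(1, 2), c(3, 4), c(k / 10, 2 - k / 15))
  })
  mn2 <- mn_of(varied)
  c1 <- random_half_control(mn2, n_samples = 70, seed = 123)
  c2 <- random_half_control(mn2, n_samples = 70, seed = 123)
  expect_identical(c1$delta, c2$delta)
  c3 <- random_half_control(mn2, n_samples = 70, seed = 124)
  expect_false(identical(c1$delta, c3$delta))

  # Monte-Carlo convergence: averaged |delta| shrinks with more samples
  few <- random_half_control(mn2, n_samples = 8, seed = 55)
  many <- random_half_control(mn2, n_samples = 512, seed = 55)
  expect_lt(mean(abs(many$delta)), mean(abs(few$delta)))
})

test_that("resolution balance test matches exact permutation enumeration", {
  # identical distributions: p near 1/2 (tie correction pushes it above)
  r <- resolution_balance_test(c(1.2, 1.5, 1.9), c(1.2, 1.5, 1.9))
  expect_gte(r$p_value, 0.5)
  expect_lte(r$p_value, 0.75)
  expect_equal(r$method, "exact enumeration")

  # extreme separation: p = 1 / choose(nA + nB, nA)
  r2 <- resolution_balance_test(rep(1.2, 3), rep(2.0, 3))
  expect_equal(r2$p_value, 1 / choose(6, 3))
  r3 <- resolution_balance_test(rep(2.0, 3), rep(1.2, 3),
                                alternative = "greater")
  expect_equal(r3$p_value, 1 / choose(6, 3))

  # exact result agrees with an independent enumeration oracle
  a <- c(1.3, 1.7, 2.0)
  b <- c(1.5, 1.6, 2.1, 1.4)
  res <- resolution_balance_test(a, b)
  pooled <- c(a, b)
  combos <- utils::combn(7, 3)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- apply(combos, 2, function(k) u_of(pooled[k], pooled[-k]))
  expect_equal(res$p_value, mean(us <= u_of(a, b)))

  # large samples switch to the normal approximation
  big <- resolution_balance_test(seq(1, 2, length.out = 30),
                                 seq(1.2, 2.2, length.out = 30))
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p_value, 0.5)

  expect_error(resolution_balance_test(numeric(), c(1)), "non-empty")
})
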