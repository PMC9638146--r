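make_collection <- function() {
  gene_set_collection(list(
    granule = c("g1", "g2", "g3", "g4", "g5"),
    adhesion = c("g4", "g5", "g6", "g7"),
    metabolism = c("g10", "g11", "g12", "g13", "g14", "g15"),
    ribosome = c("g16", "g17", "g18")),
    name = "toy")
}

test_that("over-representation p-values are exact hypergeometric tails", {
  bg <- paste0("g", 1:20)
  # perfect 5-of-5 overlap: p = 1 / C(20, 5)
  coll <- gene_set_collection(list(hit = paste0("g", 1:5)))
  res <- enrich(paste0("g", 1:5), coll, bg)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap: P(overlap >= 0) = 1
  res0 <- enrich(paste0("g", 6:10), coll, bg)
  expect_equal(res0$p_value, 1)

  # random instances against the enumeration oracle, background <= 50
  set.seed(21)
  for (i in 1:20) {
    N <- sample(15:50, 1)
    universe <- paste0("g", seq_len(N))
    term <- sample(universe, sample(3:10, 1))
    query <- sample(universe, sample(3:12, 1))
    coll_i <- gene_set_collection(list(t1 = term))
    res_i <- enrich(query, coll_i, universe)
    expect_equal(res_i$p_value,
                 oracle_hyper_tail(length(intersect(toupper(term),
                                                    toupper(query))),
                                   length(term), N, length(query)),
                 tolerance = 1e-10)
  }
})

test_that("enrichment results are complete, sorted, and validated", {
  bg <- paste0("g", 1:20)
  res <- enrich(c("g1", "g2", "g3", "g4", "g6"), make_collection(), bg)
  expect_s3_class(res, "enrichment_result")
  expect_true(all(diff(res$p_value) >= 0))
  expect_true(all(res$n_overlap <= pmin(res$n_query, res$n_term)))
  expect_true(all(res$fdr >= res$p_value))
  expect_equal(res$neg_log10_fdr, -log10(res$fdr))
  expect_error(enrich(character(0), make_collection(), bg), "empty query")
  expect_warning(enrich(c("g1", "zzz"), make_collection(), bg),
                 "outside the background")
})

test_that("BH adjustment matches the hand-evaluated step-up", {
  expect_equal(p.adjust(0.03, method = "BH"), 0.03)
  # step-up min over m/i * p with cummin from the largest p
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  expect_equal(p.adjust(rep(0.2, 5), method = "BH"), rep(0.2, 5))
  set.seed(8)
  p <- runif(12)
  o <- order(p, decreasing = TRUE)
  long <- numeric(12)
  long[o] <- pmin(cummin(12 / rank(p)[o] * p[o]), 1)
  expect_equal(p.adjust(p, method = "BH"), long)
  # order invariance
  perm <- sample(12)
  expect_equal(p.adjust(p[perm], method = "BH"),
               p.adjust(p, method = "BH")[perm])
})

test_that("kappa agrees with the contingency-table formula", {
  u <- 10
  # identical memberships -> 1; complementary -> negative
  x <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(kappa_score(x, x), 1)
  expect_true(kappa_score(x, !x) <= 0)
  # direct (Po - Pe) / (1 - Pe) on an arbitrary table a=3 b=2 c=1 d=4
  x2 <- c(rep(TRUE, 5), rep(FALSE, 5))
  y2 <- c(rep(TRUE, 3), FALSE, FALSE, TRUE, rep(FALSE, 4))
  a <- 3; b <- 2; c_ <- 1; d <- 4; n <- 10
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  expect_equal(kappa_score(x2, y2), (po - pe) / (1 - pe))
  expect_equal(kappa_score(x2, y2), kappa_score(y2, x2))  # symmetry
})

test_that("kappa grouping clusters terms sharing genes", {
  # two identical terms group together; a disjoint term stays alone
  coll <- gene_set_collection(list(
    t_a = c("g1", "g2", "g3"), t_b = c("g1", "g2", "g3"),
    t_c = c("g10", "g11", "g12")))
  bg <- paste0("g", 1:12)
  res <- enrich(c("g1", "g2", "g3"), coll, bg)
  grouped <- kappa_grouping(res, coll, kappa_threshold = 0.4, max_fdr = 1)
  gid <- setNames(grouped$kappa_group_id, grouped$term_id)
  expect_equal(gid[["t_a"]], gid[["t_b"]])
  expect_false(gid[["t_c"]] == gid[["t_a"]])
  # exactly one representative per group, the most significant term
  reps <- tapply(grouped$is_group_representative, grouped$kappa_group_id, sum)
  expect_true(all(reps == 1))
  rep_rows <- grouped[grouped$is_group_representative, ]
  for (g in unique(grouped$kappa_group_id)) {
    expect_equal(rep_rows$p_value[rep_rows$kappa_group_id == g],
                 min(grouped$p_value[grouped$kappa_group_id == g]))
  }
})

test_that("kappa grouping is order invariant and refines with the threshold", {
  set.seed(31)
  universe <- paste0("g", 1:30)
  terms <- lapply(1:8, function(i) sample(universe, sample(4:10, 1)))
  names(terms) <- paste0("t", 1:8)
  coll <- gene_set_collection(terms)
  query <- sample(universe, 10)
  res <- enrich(query, coll, universe)
  g1 <- kappa_grouping(res, coll, kappa_threshold = 0.3, max_fdr = 1)

  # permuting the collection's term order yields the same partition
  perm <- sample(8)
  coll2 <- gene_set_collection(terms[perm])
  res2 <- enrich(query, coll2, universe)
  g2 <- kappa_grouping(res2, coll2, kappa_threshold = 0.3, max_fdr = 1)
  part1 <- split(g1$term_id, g1$kappa_group_id)
  part2 <- split(g2$term_id, g2$kappa_group_id)
  norm <- function(p) sort(vapply(p, function(x)
    paste(sort(x), collapse = ","), character(1)))
  expect_equal(norm(part1), norm(part2))

  # raising the threshold never merges groups: the partition only refines
  g_lo <- kappa_grouping(res, coll, kappa_threshold = 0.2, max_fdr = 1)
  g_hi <- kappa_grouping(res, coll, kappa_threshold = 0.6, max_fdr = 1)
  lo <- setNames(g_lo$kappa_group_id, g_lo$term_id)
  hi <- setNames(g_hi$kappa_group_id, g_hi$term_id)
  for (pair in combn(g_lo$term_id, 2, simplify = FALSE)) {
    if (hi[[pair[1]]] == hi[[pair[2]]]) {
      expect_equal(lo[[pair[1]]], lo[[pair[2]]])
    }
  }
})

test_that("cluster specificity uses a strict 60% rule", {
  coll <- gene_set_collection(list(
    mostly_a = c(paste0("a", 1:7), paste0("b", 1:3)),   # 7 vs 3 -> specific_A
    split = c(paste0("a", 1:6), paste0("b", 1:4)),      # 60% not > 60%
    all_b = paste0("b", 1:5),
    no_overlap = c("z1", "z2", "z3")))
  bg <- c(paste0("a", 1:10), paste0("b", 1:10), c("z1", "z2", "z3"))
  res <- enrich(paste0("a", 1:5), coll, bg)
  res <- cluster_specificity(res, coll, cluster_a = paste0("a", 1:10),
                             cluster_b = paste0("b", 1:10))
  spec <- setNames(res$specificity, res$term_id)
  expect_equal(spec[["mostly_a"]], "specific_A")
  expect_equal(spec[["split"]], "common")
  expect_equal(spec[["all_b"]], "specific_B")
  expect_true(is.na(spec[["no_overlap"]]))
})

test_that("GMT files round-trip and report top terms", {
  coll <- make_collection()
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, name = "toy")
  expect_equal(back$term_id, coll$term_id)
  expect_equal(back$genes, lapply(coll$genes, toupper))
  bg <- paste0("g", 1:20)
  res <- enrich(c("g1", "g2", "g3"), coll, bg)
  expect_equal(nrow(top_terms(res, 2)), 2)
  expect_equal(top_terms(res, 2)$p_value, sort(res$p_value)[1:2])
  writeLines("term_only\tdesc", path)
  expect_error(read_gmt(path), "malformed GMT")
})
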