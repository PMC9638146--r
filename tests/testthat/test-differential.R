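test_that("partition is an exact three-way set decomposition", {
  p <- partition_detected(c("p1", "p2", "p3"), c("p2", "p3", "p4"))
  expect_equal(p$unique_a, "p1")
  expect_equal(p$shared, c("p2", "p3"))
  expect_equal(p$unique_b, "p4")
  expect_equal(sum(p$counts), 4)

  d <- partition_detected(c("a", "b"), c("c", "d"))
  expect_length(d$shared, 0)

  set.seed(11)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    p <- partition_detected(a, b)
    expect_equal(sum(p$counts), length(union(a, b)))       # conservation
    expect_length(intersect(p$unique_a, p$shared), 0)      # disjoint cells
    expect_length(intersect(p$unique_a, p$unique_b), 0)
    expect_equal(sum(p$pct), 100, tolerance = 1e-9)
  }
})

test_that("fold change is symmetric and classified inclusively at the cutoff", {
  fc <- fold_change(2, 1)
  expect_equal(fc$ratio, 2)
  expect_equal(fc$abs_fc, 2)
  expect_equal(as.character(fc$klass), "increased_in_A")

  fc2 <- fold_change(1, 2)
  expect_equal(fc2$abs_fc, 2)
  expect_equal(as.character(fc2$klass), "increased_in_B")

  fc3 <- fold_change(1, 1)
  expect_equal(fc3$abs_fc, 1)
  expect_equal(as.character(fc3$klass), "below_cutoff")

  # inclusive boundary: ratio exactly at the cutoff in either direction
  at <- fold_change(c(1.3, 1), c(1, 1.3), cutoff = 1.3)
  expect_equal(as.character(at$klass), c("increased_in_A", "increased_in_B"))
  just_below <- fold_change(1.2999, 1, cutoff = 1.3)
  expect_equal(as.character(just_below$klass), "below_cutoff")

  expect_error(fold_change(0, 1), "positive")

  # group swap flips labels, abs FC invariant; counts monotone in cutoff
  set.seed(5)
  a <- runif(50, 0.1, 5); b <- runif(50, 0.1, 5)
  f_ab <- fold_change(a, b); f_ba <- fold_change(b, a)
  expect_equal(f_ab$abs_fc, f_ba$abs_fc)
  expect_true(all(f_ab$abs_fc >= 1))
  swap <- c(increased_in_A = "increased_in_B",
            increased_in_B = "increased_in_A",
            below_cutoff = "below_cutoff")
  expect_equal(unname(swap[as.character(f_ab$klass)]),
               as.character(f_ba$klass))
  n_classified <- sapply(c(1.1, 1.3, 1.5, 2, 3), function(ct) {
    sum(fold_change(a, b, ct)$klass != "below_cutoff")
  })
  expect_true(all(diff(n_classified) <= 0))
})

test_that("t-tests match the closed-form oracle and handle degenerate input", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- protein_tests(list(a), list(b), method = "pooled")
  expect_equal(res$p_value, oracle_pooled_t_p(a, b), tolerance = 1e-6)

  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:13, 1), mean = runif(1))
    expect_equal(protein_tests(list(x), list(y), method = "pooled")$p_value,
                 oracle_pooled_t_p(x, y), tolerance = 1e-6)
  }

  # identical samples: t = 0, p = 1
  expect_equal(protein_tests(list(c(1, 2, 3)), list(c(1, 2, 3)))$p_value, 1)
  # zero variance in both groups with equal means -> p = 1 by convention
  expect_message(
    res0 <- protein_tests(list(c(2, 2, 2)), list(c(2, 2))),
    "zero variance")
  expect_equal(res0$p_value, 1)
  # fewer than two runs in a group -> not testable
  nt <- protein_tests(list(5), list(c(1, 2, 3)))
  expect_true(is.na(nt$p_value))
  expect_false(nt$testable)
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  # hand evaluation for m = 2: 1-(1-0.01)^2 = 0.0199, then 1-(1-0.04)^1
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(0.03), 0.03)                 # m = 1 identity
  set.seed(3)
  p <- runif(15)
  hs <- holm_sidak(p)
  expect_true(all(hs >= p))                            # never smaller
  expect_true(all(hs <= 1))
  # step-down with monotonicity, recomputed longhand
  o <- order(p)
  long <- pmin(cummax(1 - (1 - p[o])^(15 - seq_len(15) + 1)), 1)
  expect_equal(hs[o], long)
  # NA entries pass through and do not count towards m
  pna <- c(0.01, NA, 0.04)
  expect_equal(holm_sidak(pna), c(1 - 0.99^2, NA, 0.04))
})

test_that("volcano flags combine both thresholds", {
  comp <- data.frame(accession = c("a", "b", "c", "d"),
                     gene_symbol = c("A", "B", "C", "D"),
                     log2_ratio = log2(c(1.5, 1.1, 3, 1.5)),
                     abs_fc = c(1.5, 1.1, 3, 1.5),
                     p_value = c(0.04, 0.04, 0.2, NA),
                     p_adjusted = c(0.04, 0.04, 0.2, NA))
  v <- volcano_table(comp, alpha = 0.05, cutoff = 1.3)
  expect_equal(v$significant, c(TRUE, FALSE, FALSE))   # NA row dropped
  expect_equal(v$neg_log10_p[1], -log10(0.04))
})

test_that("signature matching counts classes over the whole signature", {
  m <- match_signature(c("Mpo", "Elane", " ltf ", "Ctsg"),
                       increased = c("MPO", "ELANE"), decreased = c("Ltf"))
  expect_equal(m$n_in_increased, 2)
  expect_equal(m$n_in_decreased, 1)
  expect_equal(m$n_neither, 1)
  expect_equal(m$n_in_increased + m$n_in_decreased + m$n_neither,
               length(m$signature_genes))
  expect_equal(m$pct_increased, 50)

  none <- match_signature(c("a", "b"), increased = "x", decreased = "y")
  expect_equal(none$pct_increased, 0)
  expect_equal(none$n_neither, 2)

  all_in <- match_signature(c("a", "b"), increased = c("A", "B"),
                            decreased = character(0))
  expect_equal(all_in$pct_increased, 100)

  expect_error(match_signature(character(0), "a", "b"), "empty signature")
})

test_that("signature files accept comments and blank lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# neutrophil granule proteins", "Mpo", "", "Elane  ",
               "Ltf # lactoferrin"), path)
  expect_equal(read_signature(path), c("Mpo", "Elane", "Ltf"))
})

test_that("composition profiles are percentages of the subset total", {
  db <- make_tiny_db()
  tab <- data.frame(run_id = "r1", group = "KO",
                    accession = c("P1", "P2", "P3", "P4"),
                    n_observed_peptides = c(3, 2, 1, 4),
                    stringsAsFactors = FALSE)
  q <- quantify_group(tab, db)
  # hand-computed shares on an arbitrary 2-member subset
  prof <- composition_profile(c("P1", "P2"), q)
  mm <- q$mean_molar_pct[match(c("P1", "P2"), q$accession)]
  expect_equal(prof$pct_of_subset, 100 * mm / sum(mm))
  expect_equal(sum(prof$pct_of_subset), 100, tolerance = 1e-9)
  expect_equal(composition_profile("P1", q)$pct_of_subset, 100)
  expect_error(composition_profile(character(0), q), "empty subset")
  expect_error(composition_profile("P9", q), "not quantified")
})
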