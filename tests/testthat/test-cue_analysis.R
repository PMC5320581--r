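test_that("count matrices tally GH families and carbohydrate sets per strain", {
  fx <- fixture_table2("XB6B4")
  fe <- fixture_table2("A1-86")
  m <- build_matrix(list(fx$genome, fe$genome), level = "family")
  expect_equal(rownames(m), c("RO1", "EUR"))
  expect_equal(m["RO1", "GH43"], 7L)  # Ros-2 x2, Ros-5, Ros-6 x2 (one dual), Ros-7 x2
  expect_equal(m["EUR", "GH32"], 2L)  # Eub-3, Eub-4
  expect_equal(m["EUR", "GH53"], 1L)
  expect_false("CE1" %in% colnames(m))  # family level counts GH only
  ms <- build_matrix(list(fx$genome, fe$genome), level = "carb_set")
  # GH53 genes count only under the type-1 arabinogalactan set
  expect_equal(ms["EUR", "Type-1 Arabinogalactans"], 1L)
  expect_equal(ms["EUR", "Fructans"], 2L)
  expect_equal(ms["EUR", "Alpha-glucans"], 2L)
  # empty genome gives an all-zero row
  empty <- new_genome("EMPTY", tibble::tibble(
    gene_id = "x1", contig_id = "c1", start = 1L, end = 90L, strand = "+",
    product = "hypothetical protein"))
  m2 <- build_matrix(list(fx$genome, empty), level = "family",
                     drop_empty = FALSE)
  expect_true(all(m2["EMPTY", ] == 0L))
})

test_that("Kendall distance matches a brute-force pair-count oracle", {
  expect_equal(1 - tau_b_oracle(c(1, 2, 3, 4), c(1, 3, 2, 4)), 1 / 3)
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  d <- kendall_distance(m)
  expect_equal(d["a", "b"], 1 / 3)
  # identical rows at distance 0; reversed ranks at distance 2
  m2 <- rbind(a = 1:6, b = 1:6, c = 6:1)
  d2 <- kendall_distance(m2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 2)
  # randomized rows against the oracle, with ties
  set.seed(9)
  for (r in 1:10) {
    x <- sample(0:4, 8, TRUE); y <- sample(0:4, 8, TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    d <- kendall_distance(rbind(x, y))
    expect_equal(d["x", "y"], 1 - tau_b_oracle(x, y), tolerance = 1e-12)
  }
  # constant rows get the neutral distance with a warning
  expect_warning(dc <- kendall_distance(rbind(a = c(1, 1, 1), b = 1:3)),
                 "constant")
  expect_equal(dc["a", "b"], 1)
  expect_true(isSymmetric(dc))
})

test_that("complete-linkage ecotype clustering recovers planted groups", {
  em <- generate_ecotype_matrix(generator_config(seed = 7))
  cc <- cluster_cues(em$matrix, k = 4, seed = 1)
  expect_equal(cc$n_cues, 4L)
  expect_equal(adjusted_rand(cc$assignment, em$labels), 1)
  expect_lte(cc$significance, 0.001)
  # merge heights are non-decreasing and the tree serializes to newick
  expect_true(all(diff(cc$tree$height) >= -1e-12))
  expect_match(cc$newick, "^\\(.*\\);$")
  # automatic k by the largest merge-height gap finds the same cut
  auto <- cluster_cues(em$matrix, seed = 1)
  expect_equal(auto$n_cues, 4L)
  expect_equal(adjusted_rand(auto$assignment, em$labels), 1)
  # identical strains co-cluster at height zero
  m <- em$matrix[c(1, 1, 5, 8), ]
  rownames(m) <- c("s1", "s1b", "s2", "s3")
  cc2 <- cluster_cues(m, k = 3, permutations = 99, seed = 1)
  expect_equal(cc2$assignment[["s1"]], cc2$assignment[["s1b"]])
  expect_equal(min(cc2$tree$height), 0)
  # k = 1: single ecotype, significance undefined
  cc1 <- cluster_cues(em$matrix, k = 1)
  expect_equal(cc1$n_cues, 1L)
  expect_true(is.na(cc1$significance))
  expect_error(cluster_cues(em$matrix, k = 99), "exceeds")
})

test_that("PCoA reproduces known geometry", {
  set.seed(4)
  pts <- cbind(runif(9, -3, 3), runif(9, -3, 3))
  d <- as.matrix(dist(pts))
  po <- pcoa_ordinate(d, n_axes = 5)
  # Euclidean input: first two axes carry all inertia, distances reproduced
  expect_equal(as.matrix(dist(po$coordinates[, 1:2])), d,
               tolerance = 1e-8, ignore_attr = TRUE)
  # Procrustes alignment to the generating coordinates is near-perfect
  pr <- vegan::procrustes(pts, po$coordinates[, 1:2], symmetric = TRUE)
  expect_lt(pr$ss, 1e-12)
  # points on a line: first axis explains ~100% of positive inertia
  line <- cbind(seq(0, 8), 0)
  pl <- pcoa_ordinate(as.matrix(dist(line)))
  expect_gt(pl$prop_explained[1], 0.999)
  # zero matrix gives all-zero coordinates
  pz <- pcoa_ordinate(matrix(0, 4, 4))
  expect_true(all(pz$coordinates == 0))
  # non-Euclidean distances report negative eigenvalues uncorrected
  em <- generate_ecotype_matrix(generator_config(seed = 7))
  pk <- pcoa_ordinate(kendall_distance(em$matrix))
  expect_true(any(pk$eigenvalues < 0))
})

test_that("ecotype enrichment uses one-sided exact rank-sum permutation", {
  # extreme ordering attains the minimal p for the group sizes
  x <- c(10, 9, 8, 1, 2, 3, 4, 5, 6, 7, 0)
  grp <- c(rep(TRUE, 3), rep(FALSE, 8))
  m <- cbind(set1 = x, set2 = rep(2, 11))
  rownames(m) <- sprintf("s%02d", 1:11)
  cues <- setNames(ifelse(grp, 1, 2), rownames(m))
  enr <- enrichment_by_cue(m, cues)
  p_min <- 1 / choose(11, 3)
  expect_equal(enr$p[enr$cue == 1 & enr$set == "set1"], p_min)
  # identical counts everywhere give p = 1
  expect_equal(enr$p[enr$cue == 1 & enr$set == "set2"], 1)
  # planted xylan-type shift is detected in most replicates
  hits <- 0L
  for (s in 1:40) {
    em <- generate_ecotype_matrix(generator_config(seed = s))
    cc <- cluster_cues(em$matrix, k = 4, permutations = 99, seed = s)
    e <- enrichment_by_cue(em$matrix, cc)
    grp2 <- names(em$labels)[em$labels == 2]
    cue2 <- unique(cc$assignment[grp2])
    sig_cols <- colnames(em$matrix)[5:8]  # group 2 signature columns
    pv <- e$p[e$cue == cue2 & e$set %in% sig_cols]
    if (all(pv < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("genotype-phenotype concordance flags the single inulin exception", {
  growth <- fixture_growth_matrix()
  presence <- fixture_pul_presence()
  pairs <- tibble::tibble(pul_family = "Eub-3", substrate = "inulin")
  rep <- phenotype_concordance(presence, growth, pairs)
  expect_equal(nrow(rep), 1L)
  excs <- strsplit(rep$exceptions, ";")[[1]]
  expect_equal(length(excs), 1L)
  expect_match(excs, "M72/1")
  expect_match(excs, "pseudogenized")
  expect_equal(rep$n_present_growth, 5L)
  # substrate absent from the table is skipped with a warning
  expect_warning(
    empty <- phenotype_concordance(presence, growth,
                                   tibble::tibble(pul_family = "Eub-3",
                                                  substrate = "nope")),
    "absent")
  expect_equal(nrow(empty), 0L)
  # perfectly concordant synthetic pair: no exceptions
  pres2 <- tibble::tibble(pul_family = "P", strain_id = rownames(growth),
                          present = growth[, "FOS"], pseudo = FALSE)
  rep2 <- phenotype_concordance(pres2, growth,
                                tibble::tibble(pul_family = "P",
                                               substrate = "FOS"))
  expect_equal(rep2$exceptions, "")
  expect_equal(rep2$reverse_exceptions, "")
})

test_that("PERMANOVA under an exchangeable null is calibrated", {
  set.seed(20)
  n_sim <- 300
  rej <- 0L
  for (i in seq_len(n_sim)) {
    m <- matrix(rpois(11 * 12, 3), 11)
    rownames(m) <- sprintf("s%02d", 1:11)
    d <- kendall_distance(m)
    lab <- factor(sample(rep(1:4, c(4, 3, 2, 2))))
    p <- vegan::adonis2(stats::as.dist(d) ~ g, data = data.frame(g = lab),
                        permutations = 99)$`Pr(>F)`[1]
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_sim, 0.02)
  expect_lte(rej / n_sim, 0.08)
})
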