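test_that("the generator is deterministic and honours its truth table", {
  cfg <- generator_config(seed = 19)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$genome$genes, b$genome$genes)
  expect_identical(a$genome$labels, b$genome$labels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$hmm, b$hmm)
  expect_equal(n_genes(a$genome), cfg$genes_per_genome)
  expect_equal(nrow(a$truth), cfg$n_planted_puls)
  # planted loci are flanked by >= 3 non-carbohydrate genes
  carb <- gppulr:::carb_related_flags(a$genome, detection_params())
  rk <- a$genome$genes$rank
  for (i in seq_len(nrow(a$truth))) {
    lo <- a$truth$first_rank[i]; hi <- a$truth$last_rank[i]
    left <- carb[rk >= lo - 3 & rk < lo]
    right <- carb[rk > hi & rk <= hi + 3]
    expect_false(any(left))
    expect_false(any(right))
  }
  # lone-GH decoys sit >= 11 genes from any transporter component
  tc <- genes_with_category(a$genome, "TRANSPORT_COMPONENT")
  tc_ranks <- a$genome$genes$rank[a$genome$genes$gene_id %in% tc]
  lone <- a$decoys[a$decoys$decoy_type == "decoy_lone_gh", ]
  for (i in seq_len(nrow(lone))) {
    expect_true(all(abs(tc_ranks - lone$first_rank[i]) >= 11))
  }
})

test_that("zero planted loci yield zero detections", {
  g <- generate_genome(generator_config(seed = 23, n_planted_puls = 0,
                                        n_decoys = 2))
  expect_equal(nrow(g$truth), 0L)
  expect_equal(nrow(detect_gppuls(g$genome)), 0L)
})

test_that("mock evidence rows pass for planted enzymes and fail for decoy rows", {
  g <- generate_genome(generator_config(seed = 31))
  t <- filter_thresholds()
  kept_h <- filter_hmm_hits(g$hmm, t)
  kept_b <- filter_blast_hits(g$blast, t)
  caz <- g$genome$labels[g$genome$labels$category %in% c("GH", "CE", "PL"), ]
  expect_setequal(kept_h$gene_id, unique(caz$gene_id))
  expect_true(all(kept_b$gene_id %in% caz$gene_id))
  # the failing fraction was really injected and really fails
  expect_gt(nrow(g$hmm), nrow(kept_h))
  expect_gt(nrow(g$blast), nrow(kept_b))
})

test_that("the full pipeline recovers planted loci from raw evidence", {
  g <- generate_genome(generator_config(seed = 37),
                       include_enzyme_labels = FALSE)
  # before calling, no GH labels exist and nothing is detectable
  expect_equal(length(genes_with_category(g$genome, "GH")), 0L)
  expect_equal(nrow(detect_gppuls(g$genome)), 0L)
  res <- call_cazymes(g$genome, g$hmm, g$blast)
  puls <- detect_gppuls(res$genome)
  expect_equal(nrow(puls), nrow(g$truth))
  expect_equal(puls$first_rank, g$truth$first_rank)
  expect_equal(puls$last_rank, g$truth$last_rank)
})

test_that("published-locus fixtures encode the printed compositions", {
  fx <- fixture_table2("XB6B4")
  expect_equal(nrow(fx$truth), 10L)
  expect_equal(fx$truth$pul_name, sprintf("Ros-%d", 1:10))
  fe <- fixture_table2("A1-86")
  expect_equal(nrow(fe$truth), 4L)
  # Ros-5 contains two ABC systems
  sys <- find_transporter_systems(fx$genome)
  r5 <- fx$truth[fx$truth$pul_name == "Ros-5", ]
  in_r5 <- sys[sys$first_rank >= r5$first_rank &
                 sys$last_rank <= r5$last_rank, ]
  expect_equal(nrow(in_r5), 2L)
  expect_equal(in_r5$family, c("ABC", "ABC"))
  # dual-family entries are single genes with two family labels
  lab <- fx$genome$labels
  dual <- lab[lab$family %in% c("GH78", "GH15"), ]
  expect_equal(length(unique(dual$gene_id)), 1L)
  # Eub-2 uses a single-gene GPH system
  sys_e <- find_transporter_systems(fe$genome)
  expect_true(any(sys_e$family == "GPH" & sys_e$n_members == 1))
  # the fixture is deterministic
  expect_identical(fixture_table2("XB6B4")$genome$genes, fx$genome$genes)
})

test_that("ecotype matrices carry the planted structure", {
  cfg <- generator_config(seed = 7)
  em <- generate_ecotype_matrix(cfg)
  expect_equal(dim(em$matrix), c(11L, 16L))
  expect_equal(unname(table(em$labels)), c(4L, 3L, 2L, 2L),
               ignore_attr = TRUE)
  expect_identical(generate_ecotype_matrix(cfg)$matrix, em$matrix)
  # zero jitter: within-group rows are identical
  em0 <- generate_ecotype_matrix(generator_config(seed = 7, jitter = 0))
  for (k in 1:4) {
    rows <- em0$matrix[em0$labels == k, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  # zero shift: no recoverable structure (PERMANOVA p roughly uniform)
  set.seed(41)
  ps <- vapply(1:40, function(s) {
    emn <- generate_ecotype_matrix(generator_config(seed = s, shift = 0))
    d <- kendall_distance(emn$matrix)
    vegan::adonis2(stats::as.dist(d) ~ g,
                   data = data.frame(g = factor(emn$labels)),
                   permutations = 99)$`Pr(>F)`[1]
  }, numeric(1))
  expect_gt(mean(ps <= 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps <= 0.05), 0.25)
})

test_that("the growth fixture matches the published statements", {
  m <- fixture_growth_matrix()
  expect_equal(dim(m), c(10L, 14L))
  expect_true(all(m[, "FOS"]))
  expect_false(any(m[, c("beta-mannan", "xyloglucan",
                         "arabinogalactan_type2", "mucin_type2",
                         "mucin_type3")]))
  expect_false(m["A2-183", "amylopectin"])
  expect_false(m["A2-183", "amylose"])
  expect_true(all(m[c("A1-86", "M104/1", "T1-815", "A2-194", "L1-83"),
                    "inulin"]))
  expect_false(any(m[c("L1-82", "M50/1", "XB6B4", "A2-183", "M72/1"),
                     "inulin"]))
  expect_equal(sum(m[, "arabinogalactan_type1"]), 1L)
  expect_true(m["M72/1", "arabinogalactan_type1"])
})
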