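test_that("transporter systems are maximal contiguous runs split by family", {
  g <- toy_genome(c("O", "ABC", "ABC", "ABC", "GH13", "ABC", "ABC", "O",
                    "GPH", "O", "ABC", "MFS"))
  sys <- find_transporter_systems(g)
  expect_equal(nrow(sys), 5L)
  expect_equal(sys$family, c("ABC", "ABC", "GPH", "ABC", "MFS"))
  expect_equal(sys$n_members, c(3L, 2L, 1L, 1L, 1L))
  expect_equal(sys$first_rank, c(1L, 5L, 8L, 10L, 11L))
  # lone components are systems of size one
  expect_true(all(sys$n_members >= 1))
})

test_that("seeding distance is a strict 11-gene rule on rank differences", {
  # GH at rank 0; nearest ABC member at rank 10 (distance 10) and, in a
  # second genome, at rank 11 (distance 11)
  g10 <- toy_genome(c("GH13", rep("O", 9), "ABC", "ABC"))
  g11 <- toy_genome(c("GH13", rep("O", 10), "ABC", "ABC"))
  s10 <- seed_candidates(g10, find_transporter_systems(g10))
  s11 <- seed_candidates(g11, find_transporter_systems(g11))
  expect_equal(nrow(s10), 1L)
  expect_equal(s10$distance, 10L)
  expect_equal(nrow(s11), 0L)
  # inclusive switch admits distance 11
  s11i <- seed_candidates(g11, find_transporter_systems(g11),
                          detection_params(inclusive_distance = TRUE))
  expect_equal(nrow(s11i), 1L)
  # different contigs never seed
  genes <- g10$genes; genes$contig_id[genes$gene_id == "TOY_001"] <- "c2"
  g2 <- new_genome("TOY", genes, g10$labels)
  expect_equal(nrow(seed_candidates(g2, find_transporter_systems(g2))), 0L)
})

test_that("boundary rule: three non-carbohydrate genes split, two do not", {
  locusA <- c("GH13", "ABC", "ABC", "REG:LacI")
  locusB <- c("GH32", "ABC", "ABC", "REG:AraC")
  flank <- rep("O", 3)
  split2 <- toy_genome(c(flank, locusA, rep("O", 3), locusB, flank))
  merged <- toy_genome(c(flank, locusA, rep("O", 2), locusB, flank))
  p_split <- extend_and_call(split2)
  p_merge <- extend_and_call(merged)
  expect_equal(nrow(p_split), 2L)
  expect_equal(p_split$first_rank, c(3L, 10L))
  expect_equal(p_split$last_rank, c(6L, 13L))
  # hand-trace: with a 2-gene gap the scanner cannot stop, so one locus
  # spans ranks 3..12 including the two internal background genes
  expect_equal(nrow(p_merge), 1L)
  expect_equal(p_merge$first_rank, 3L)
  expect_equal(p_merge$last_rank, 12L)
  expect_equal(p_merge$n_genes, 10L)
  expect_equal(p_merge$transporter_families, "ABC;ABC")
})

test_that("the three-component validity rule rejects incomplete clusters", {
  # GH + transporter but no regulator
  no_reg <- toy_genome(c(rep("O", 3), "GH13", "ABC", "ABC", rep("O", 3)))
  expect_equal(nrow(extend_and_call(no_reg)), 0L)
  # transporter + regulator but no GH/CE/PL enzyme (CARB_METABOLISM does
  # not fill the enzyme slot)
  no_enz <- toy_genome(c(rep("O", 3), "XYL", "ABC", "ABC", "REG:LacI",
                         rep("O", 3)))
  expect_equal(nrow(extend_and_call(no_enz)), 0L)
  # regulator outside the recognised vocabulary does not count
  odd_reg <- toy_genome(c(rep("O", 3), "GH13", "ABC", "ABC", "REG:WhiB",
                          rep("O", 3)))
  expect_equal(nrow(extend_and_call(odd_reg)), 0L)
  # all three present: called
  ok <- toy_genome(c(rep("O", 3), "GH13", "ABC", "ABC", "REG:LacI",
                     rep("O", 3)))
  expect_equal(nrow(extend_and_call(ok)), 1L)
})

test_that("emitted loci never contain or abut a three-gene non-carb run", {
  set.seed(5)
  for (s in 1:5) {
    g <- generate_genome(generator_config(seed = s))
    puls <- extend_and_call(g$genome)
    carb <- gppulr:::carb_related_flags(g$genome, detection_params())
    rk <- g$genome$genes$rank
    for (i in seq_len(nrow(puls))) {
      inside <- carb[rk >= puls$first_rank[i] & rk <= puls$last_rank[i]]
      runs <- rle(!inside)
      expect_true(all(runs$lengths[runs$values] < 3))
      expect_true(inside[1] && inside[length(inside)])
    }
  }
})

test_that("detection is invariant under contig reversal", {
  fx <- fixture_table2("A1-86")
  fwd <- detect_gppuls(fx$genome)
  n <- n_genes(fx$genome)
  genes <- fx$genome$genes
  # mirror coordinates so gene order (and ranks) reverse
  genes$new_start <- (n * 1000L) - genes$end + 1L
  genes$end <- (n * 1000L) - genes$start + 1L
  genes$start <- genes$new_start
  genes$new_start <- NULL
  genes$strand <- ifelse(genes$strand == "+", "-", "+")
  rev_g <- new_genome(fx$genome$strain_id, genes, fx$genome$labels)
  rev <- detect_gppuls(rev_g)
  expect_equal(nrow(rev), nrow(fwd))
  members <- function(p) sort(vapply(p$member_genes, function(m)
    paste(sort(strsplit(m, ";")[[1]]), collapse = "+"), character(1)))
  expect_equal(unname(members(rev)), unname(members(fwd)))
})

test_that("substrate prediction unions member sets and grades confidence", {
  fx <- fixture_table2("XB6B4")
  puls <- detect_gppuls(fx$genome, set_map = default_carb_set_map())
  # a locus whose enzymes span many sets is not confident
  wide <- toy_genome(c(rep("O", 3), "GH13", "GH32", "GH28", "GH29", "ABC",
                       "ABC", "REG:LacI", rep("O", 3)))
  pw <- detect_gppuls(wide, set_map = default_carb_set_map())
  expect_equal(nrow(pw), 1L)
  expect_false(pw$confident)
  expect_setequal(strsplit(pw$predicted_substrates, ";")[[1]],
                  c("Alpha-glucans", "Fructans", "Pectins", "Host glycans"))
  # a locus with only unmapped families predicts nothing
  unk <- toy_genome(c(rep("O", 3), "GH999", "ABC", "ABC", "REG:LacI",
                      rep("O", 3)))
  pu <- suppressMessages(detect_gppuls(unk, set_map = default_carb_set_map()))
  expect_equal(pu$predicted_substrates, "")
  expect_false(pu$confident)
})

test_that("cross-strain locus comparison applies the half-overlap rule", {
  # three strains carry the same planted locus; one shares a single gene
  tpl <- table2_templates("A1-86")[[3]]  # Eub-3
  mk <- function(strain, seed) {
    g <- generate_genome(generator_config(seed = seed, n_planted_puls = 1,
                                          n_decoys = 0),
                         templates = list(tpl), strain_id = strain)
    g
  }
  g1 <- mk("S1", 101); g2 <- mk("S2", 102); g3 <- mk("S3", 103)
  p1 <- detect_gppuls(g1$genome); p2 <- detect_gppuls(g2$genome)
  p3 <- detect_gppuls(g3$genome)
  # orthology ground truth: same template position -> same OG
  ogs <- list()
  for (g in list(g1, g2, g3)) {
    genes <- strsplit(g$truth$gene_ids, ";")[[1]]
    gl <- g$genome$labels[match(genes, g$genome$labels$gene_id), ]
    ogs[[length(ogs) + 1]] <- tibble::tibble(gene_id = genes,
                                             strain_id = g$genome$strain_id)
  }
  ogs <- dplyr::bind_rows(ogs)
  # assign OGs by role signature within the locus (each template slot is
  # one OG across strains)
  sig <- function(g, ids) {
    lab <- g$genome$labels
    vapply(ids, function(id) {
      r <- lab[lab$gene_id == id, ]
      paste0(r$category[1], "_", r$family[1])
    }, character(1))
  }
  sigs <- c(sig(g1, strsplit(g1$truth$gene_ids, ";")[[1]]),
            sig(g2, strsplit(g2$truth$gene_ids, ";")[[1]]),
            sig(g3, strsplit(g3$truth$gene_ids, ";")[[1]]))
  # disambiguate repeated signatures within a strain deterministically
  ogs$og_id <- paste0("OG_", ave(sigs, paste(ogs$strain_id, sigs),
                                 FUN = seq_along), sigs)
  ogs$n_strains <- 3L; ogs$status <- "core"
  cmp <- compare_puls_across_strains(list(p1, p2, p3), ogs)
  expect_equal(nrow(cmp$families), 3L)
  expect_equal(length(unique(cmp$families$family_id)), 1L)
  expect_true(all(cmp$pairs$orthologous))
  expect_true(all(cmp$presence))
  # below-half overlap is not orthologous
  pr <- cmp$pairs
  expect_true(all(pr$overlap >= 0.5))
})
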