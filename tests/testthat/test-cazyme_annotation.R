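test_that("HMM filter applies the dual-length e-value rule and strict coverage", {
  hits <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    family = "GH13",
    evalue = c(5e-4, 5e-4, 1e-6, 1e-6, 2e-3),
    aln_len = c(60L, 100L, 100L, 100L, 60L),
    coverage = c(0.4, 0.4, 0.3, 0.31, 0.4))
  kept <- filter_hmm_hits(hits)
  # short alignment tolerates 5e-4; long does not; coverage 0.3 is excluded
  expect_setequal(kept$gene_id, c("g1", "g4"))
  expect_error(filter_hmm_hits(tibble::tibble(
    gene_id = "g", family = "GH1", evalue = -1, aln_len = 10L,
    coverage = 0.5)), "negative")
})

test_that("protein-search filter keeps boundary values and drops each failure mode", {
  hits <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    subject_annotation = "3.2.1.8",
    evalue = c(1e-12, 1e-12, 1e-9, 1e-10, 1e-12),
    identity_pct = c(40, 34.9, 90, 35, 40),
    bitscore = c(250, 250, 900, 200, 199))
  kept <- filter_blast_hits(hits)
  expect_setequal(kept$gene_id, c("g1", "g4"))
  expect_error(filter_blast_hits(tibble::tibble(
    gene_id = "g", subject_annotation = "x", evalue = 1e-20,
    identity_pct = 101, bitscore = 300)), "identity")
})

test_that("filters are idempotent, subset-producing and threshold-monotone", {
  set.seed(42)
  n <- 120
  hmm <- tibble::tibble(
    gene_id = sprintf("h%03d", 1:n), family = "GH43",
    evalue = 10^runif(n, -12, 0), aln_len = sample(20:300, n, TRUE),
    coverage = runif(n))
  blast <- tibble::tibble(
    gene_id = sprintf("b%03d", 1:n), subject_annotation = "3.2.1.37",
    evalue = 10^runif(n, -30, 0), identity_pct = runif(n, 0, 100),
    bitscore = runif(n, 0, 600))
  t0 <- filter_thresholds()
  expect_identical(filter_hmm_hits(filter_hmm_hits(hmm, t0), t0),
                   filter_hmm_hits(hmm, t0))
  expect_identical(filter_blast_hits(filter_blast_hits(blast, t0), t0),
                   filter_blast_hits(blast, t0))
  expect_true(all(filter_hmm_hits(hmm, t0)$gene_id %in% hmm$gene_id))
  tighter <- filter_thresholds(blast_min_identity = 50,
                               blast_min_bitscore = 300,
                               hmm_max_e_short = 1e-4, hmm_max_e_long = 1e-6,
                               hmm_min_coverage = 0.5)
  expect_true(all(filter_hmm_hits(hmm, tighter)$gene_id %in%
                    filter_hmm_hits(hmm, t0)$gene_id))
  expect_true(all(filter_blast_hits(blast, tighter)$gene_id %in%
                    filter_blast_hits(blast, t0)$gene_id))
})

test_that("dual-evidence calling merges HMM families, CBMs and EC annotations", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5), contig_id = "c1",
    start = seq(1L, by = 100L, length.out = 5),
    end = seq(90L, by = 100L, length.out = 5), strand = "+",
    product = "protein")
  g <- new_genome("S", genes)
  hmm <- tibble::tibble(
    gene_id = c("g1", "g1", "g3", "g4"),
    family = c("GH13", "CBM41", "GH5", "GH32"),
    evalue = c(1e-20, 1e-20, 1e-2, 1e-20),  # g3 fails the long-aln rule
    aln_len = c(200L, 90L, 200L, 150L),
    coverage = c(0.9, 0.8, 0.9, 0.8))
  blast <- tibble::tibble(
    gene_id = c("g2", "g3", "g4"),
    subject_annotation = c("3.2.1.8", "3.2.1.4", "3.2.1.26"),
    evalue = c(1e-40, 1e-3, 1e-40),         # g3 fails the e-value rule
    identity_pct = c(60, 80, 70), bitscore = c(400, 400, 350))
  res <- call_cazymes(g, hmm, blast, sp_flags = c(g1 = TRUE))
  calls <- res$calls
  expect_setequal(calls$gene_id, c("g1", "g2", "g4"))  # g3, g5: no call
  expect_equal(calls$families[calls$gene_id == "g1"], "GH13")
  expect_equal(calls$cbms[calls$gene_id == "g1"], "CBM41")
  expect_true(calls$has_signal_peptide[calls$gene_id == "g1"])
  # protein-search-only gene: empty families, GH inferred from EC 3.2.1.-
  expect_equal(calls$families[calls$gene_id == "g2"], "")
  expect_equal(calls$ec_annotations[calls$gene_id == "g2"], "3.2.1.8")
  lab <- res$genome$labels
  expect_true(any(lab$gene_id == "g2" & lab$category == "GH" &
                    lab$ec == "3.2.1.8"))
  expect_true(any(lab$gene_id == "g1" & lab$category == "CBM" &
                    lab$family == "CBM41"))
  expect_false(any(lab$gene_id %in% c("g1", "g2", "g4") &
                     lab$category == "OTHER"))
  # unknown gene_id in evidence is skipped with a warning
  expect_warning(call_cazymes(g, dplyr::bind_rows(
    hmm, tibble::tibble(gene_id = "nope", family = "GH1", evalue = 1e-20,
                        aln_len = 100L, coverage = 0.9)), NULL),
    "unknown gene_id")
})

test_that("carbohydrate sets: family rule, EC fallback and the GH53 override", {
  calls <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    families = c("GH13", "GH53", "", "GH2", "GH43;GH53"),
    cbms = "",
    ec_annotations = c("", "3.2.1.89", "", "3.2.1.23", ""),
    has_signal_peptide = FALSE, n_evidence = 1L)
  sets <- suppressMessages(assign_carbohydrate_sets(calls))
  expect_equal(sets[["a"]], "Alpha-glucans")
  expect_equal(sets[["b"]], "Type-1 Arabinogalactans")
  expect_equal(sets[["c"]], character(0))
  # family unmapped -> EC fallback
  expect_equal(sets[["d"]], "Alpha- and Beta-galactosides")
  # GH53 exclusivity even for a dual-family gene
  expect_equal(sets[["e"]], "Type-1 Arabinogalactans")
  # no gene is ever in both the type-1 arabinogalactan set and Pectins
  set.seed(7)
  fams <- names(default_carb_set_map()$family_sets)
  rnd <- tibble::tibble(
    gene_id = sprintf("r%03d", 1:100),
    families = vapply(1:100, function(i)
      paste(sample(fams, sample(1:3, 1)), collapse = ";"), character(1)),
    cbms = "", ec_annotations = "", has_signal_peptide = FALSE,
    n_evidence = 1L)
  rs <- suppressMessages(assign_carbohydrate_sets(rnd))
  both <- vapply(rs, function(s)
    all(c("Type-1 Arabinogalactans", "Pectins") %in% s), logical(1))
  expect_false(any(both))
})

test_that("the shipped YAML map equals the built-in default", {
  path <- system.file("extdata", "carb_sets.yaml", package = "gppulr")
  y <- read_carb_set_map(path)
  d <- default_carb_set_map()
  expect_equal(y$family_sets[order(names(y$family_sets))],
               d$family_sets[order(names(d$family_sets))])
  expect_equal(y$ec_sets[order(names(y$ec_sets))],
               d$ec_sets[order(names(d$ec_sets))])
  expect_equal(y$t1ag_excluded, d$t1ag_excluded)
})
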