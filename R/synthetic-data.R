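#' Locus template for the synthetic generator
#'
#' Describes a gpPUL's composition: enzymes (with optional per-gene EC and
#' dual families), transporter systems, regulators, accessory
#' carbohydrate-metabolism genes and up to two internal hypothetical
#' genes. Templates satisfy the minimum-component rule by construction and
#' must contain at least one GH gene so the locus is seedable.
#'
#' @param name Template name (e.g. `"Ros-2"`).
#' @param enzymes List; each element a list with `families` (character,
#'   one or two CAZy families) and optional `ec`.
#' @param transporters List; each element a list with `family`
#'   (`ABC`/`GPH`/`MFS`/`PTS`) and `n_components`.
#' @param regulators Character vector of regulator family strings.
#' @param accessory Character vector of carbohydrate-metabolism gene roles
#'   (free text, e.g. `"xylose isomerase"`).
#' @param internal_hypotheticals Integer, at most 2.
#' @return A list of class `pul_template`.
#' @export
pul_template <- function(name, enzymes, transporters, regulators,
                         accessory = character(),
                         internal_hypotheticals = 0L) {
  stopifnot(length(enzymes) >= 1, length(transporters) >= 1,
            length(regulators) >= 1, internal_hypotheticals <= 2)
  has_gh <- any(vapply(enzymes, function(e) any(grepl("^GH", e$families)),
                       logical(1)))
  if (!has_gh) stop("template must contain at least one GH enzyme")
  structure(list(name = name, enzymes = enzymes, transporters = transporters,
                 regulators = regulators, accessory = accessory,
                 internal_hypotheticals = as.integer(internal_hypotheticals)),
            class = "pul_template")
}

enz <- function(families, ec = NA_character_) list(families = families, ec = ec)
trsp <- function(family, n_components) list(family = family,
                                            n_components = n_components)

#' Published locus compositions as templates
#'
#' The ten confidently-predicted loci of *R. intestinalis* XB6B4
#' (Ros-1..Ros-10) and the four of *E. rectale* A1-86 (Eub-1..Eub-4), with
#' enzyme complements, transporter systems and regulator families as
#' printed. Dual-family entries (GH78/15, GH43/51) are single genes
#' carrying both family labels; the Ros-9 esterase entry is encoded as
#' CE1. ECs are attached where the source text names them (GH43 xylosidase
#' 3.2.1.37, GH28 polygalacturonase 3.2.1.15, GH53 galactanase 3.2.1.89,
#' GH32 beta-fructofuranosidase 3.2.1.26) plus a beta-mannanase EC
#' (3.2.1.78) for the Ros-9 GH5, consistent with that locus's printed
#' glucomannan substrate.
#'
#' @param strain `"XB6B4"` or `"A1-86"`.
#' @return List of [pul_template()] objects.
#' @export
table2_templates <- function(strain = c("XB6B4", "A1-86")) {
  strain <- match.arg(strain)
  if (strain == "XB6B4") {
    list(
      pul_template("Ros-1",
                   list(enz("GH29"), enz("GH42")),
                   list(trsp("ABC", 3)), "HK"),
      pul_template("Ros-2",
                   list(enz("GH28", "3.2.1.15"), enz("GH43", "3.2.1.37"),
                        enz("GH43", "3.2.1.37"), enz("CE12")),
                   list(trsp("ABC", 3)), "AraC",
                   accessory = "xylose isomerase"),
      pul_template("Ros-3",
                   list(enz("GH1"), enz("GH36"), enz("GH76"), enz("GH113"),
                        enz("GH130"), enz("GH130"), enz("CE2"), enz("CE3")),
                   list(trsp("ABC", 3)), c("AraC", "LacI")),
      pul_template("Ros-4",
                   list(enz("GH13"), enz("GH77"), enz(c("GH78", "GH15"))),
                   list(trsp("ABC", 3)), c("AsrR", "LacI")),
      pul_template("Ros-5",
                   list(enz("GH2"), enz("GH3"), enz("GH8"), enz("GH42"),
                        enz("GH43"), enz("GH53", "3.2.1.89"), enz("GH115")),
                   list(trsp("ABC", 3), trsp("ABC", 3)),
                   c("HK", "RR_AraC_CheY", "LacI", "AraC")),
      pul_template("Ros-6",
                   list(enz("GH39"), enz("GH39"), enz(c("GH43", "GH51")),
                        enz("GH43"), enz("GH51"), enz("GH51"), enz("GH120"),
                        enz("CE1"), enz("CE1")),
                   list(trsp("ABC", 3)), c("LacI", "AraC")),
      pul_template("Ros-7",
                   list(enz("GH25"), enz("GH43"), enz("GH43"), enz("GH51")),
                   list(trsp("ABC", 3), trsp("GPH", 1)),
                   c("AraC", "MCST", "RR_LytTR", "HK")),
      pul_template("Ros-8",
                   list(enz("GH51"), enz("GH127")),
                   list(trsp("ABC", 3)), "TetR"),
      pul_template("Ros-9",
                   list(enz("GH2"), enz("GH5", "3.2.1.78"),
                        enz("GH53", "3.2.1.89"), enz("GH130"), enz("CE1")),
                   list(trsp("ABC", 3), trsp("ABC", 3)), "LacI"),
      pul_template("Ros-10",
                   list(enz("GH3"), enz("GH38"), enz("GH85"), enz("GH125"),
                        enz("GH130"), enz("GH20"), enz("CE1")),
                   list(trsp("ABC", 3), trsp("MFS", 1)),
                   c("LacI", "LacI", "NagC", "NagC"))
    )
  } else {
    list(
      pul_template("Eub-1",
                   list(enz("GH31"), enz("GH31")),
                   list(trsp("ABC", 3)), "LacI"),
      pul_template("Eub-2",
                   list(enz("GH2"), enz("GH53", "3.2.1.89")),
                   list(trsp("GPH", 1)), "AraC"),
      pul_template("Eub-3",
                   list(enz("GH32", "3.2.1.26")),
                   list(trsp("ABC", 3)), "LacI",
                   accessory = "fructokinase"),
      pul_template("Eub-4",
                   list(enz("GH32", "3.2.1.26")),
                   list(trsp("ABC", 3)), "LacI")
    )
  }
}

#' Generator configuration
#'
#' Defaults define the study conditions the synthetic suite runs under:
#' 200-gene single-contig genomes, three planted loci drawn from the
#' published templates, two decoys (a lone GH at least 11 genes from any
#' transporter, and a GH-plus-transporter cluster with no regulator), and
#' ecotype matrices with 11 strains in groups of 4/3/2/2 over 16
#' carbohydrate-set columns (four signature columns per group), a
#' between-group signature shift of 5 counts over a baseline of 2, and
#' integer jitter of 1.
#'
#' @param genes_per_genome,n_planted_puls,n_decoys Genome generator knobs.
#' @param evidence_fail_fraction Fraction of background genes that receive
#'   deliberately sub-threshold mock evidence rows.
#' @param group_sizes,n_cols,signature_cols_per_group,base_count,shift,jitter
#'   Ecotype-matrix generator knobs.
#' @param seed Mandatory seed for any stochastic output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(genes_per_genome = 200L, n_planted_puls = 3L,
                             n_decoys = 2L, evidence_fail_fraction = 0.1,
                             group_sizes = c(4L, 3L, 2L, 2L), n_cols = 16L,
                             signature_cols_per_group = 4L, base_count = 2L,
                             shift = 5L, jitter = 1L, seed = 1L) {
  stopifnot(genes_per_genome > 0, n_planted_puls >= 0, n_decoys >= 0,
            shift >= 0, jitter >= 0, length(seed) == 1, is.finite(seed))
  structure(list(genes_per_genome = as.integer(genes_per_genome),
                 n_planted_puls = as.integer(n_planted_puls),
                 n_decoys = as.integer(n_decoys),
                 evidence_fail_fraction = evidence_fail_fraction,
                 group_sizes = as.integer(group_sizes),
                 n_cols = as.integer(n_cols),
                 signature_cols_per_group = as.integer(signature_cols_per_group),
                 base_count = as.integer(base_count),
                 shift = as.integer(shift), jitter = as.integer(jitter),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Component family strings for a transporter system spec.
transporter_components <- function(family, n) {
  if (family == "ABC") {
    rep(c("ABC_SBP", "ABC_permease", "ABC_ATPase"), length.out = n)
  } else {
    rep(family, n)
  }
}

# Realize a template as a list of gene specs (role/category/family/ec).
# `shuffle` randomizes internal order under the constraints that the locus
# starts and ends on carbohydrate-related non-hypothetical genes and every
# GH gene lies within `max_dist` of a transporter component.
realize_template <- function(template, shuffle = FALSE, max_dist = 11L) {
  specs <- list()
  for (e in template$enzymes) {
    specs[[length(specs) + 1]] <- list(role = "enzyme",
                                       families = e$families, ec = e$ec)
  }
  sys_specs <- lapply(seq_along(template$transporters), function(k) {
    tr <- template$transporters[[k]]
    lapply(transporter_components(tr$family, tr$n_components), function(f) {
      list(role = "transporter", families = f, ec = NA_character_)
    })
  })
  reg_specs <- lapply(template$regulators, function(r) {
    list(role = "regulator", families = r, ec = NA_character_)
  })
  acc_specs <- lapply(template$accessory, function(a) {
    list(role = "accessory", families = NA_character_, ec = NA_character_,
         product = a)
  })
  hyp_specs <- if (template$internal_hypotheticals > 0) {
    lapply(seq_len(template$internal_hypotheticals), function(i) {
      list(role = "hypothetical", families = NA_character_,
           ec = NA_character_)
    })
  } else list()

  if (!shuffle) {
    # deterministic layout: first half of the enzymes, accessory, first
    # system, first half of the regulators, remaining enzymes, remaining
    # systems, remaining regulators; hypotheticals interleaved mid-locus
    ne <- length(specs); nr <- length(reg_specs)
    e1 <- specs[seq_len(ceiling(ne / 2))]
    e2 <- specs[setdiff(seq_len(ne), seq_len(ceiling(ne / 2)))]
    r1 <- reg_specs[seq_len(ceiling(nr / 2))]
    r2 <- reg_specs[setdiff(seq_len(nr), seq_len(ceiling(nr / 2)))]
    rest_sys <- if (length(sys_specs) > 1) {
      unlist(sys_specs[-1], recursive = FALSE)
    } else list()
    ordered <- c(e1, acc_specs, hyp_specs, sys_specs[[1]], r1, e2, rest_sys,
                 r2)
    return(ordered)
  }
  # randomized order, resampled until the constraints hold
  flat_sys <- unlist(sys_specs, recursive = FALSE)
  all_specs <- c(specs, acc_specs, reg_specs, flat_sys, hyp_specs)
  repeat {
    ord <- sample(length(all_specs))
    cand <- all_specs[ord]
    roles <- vapply(cand, function(s) s$role, character(1))
    if (roles[1] == "hypothetical" ||
        roles[length(roles)] == "hypothetical") next
    gh_pos <- which(vapply(cand, function(s)
      s$role == "enzyme" && any(grepl("^GH", s$families)), logical(1)))
    tr_pos <- which(roles == "transporter")
    ok <- all(vapply(gh_pos, function(p) min(abs(p - tr_pos)) < max_dist,
                     logical(1)))
    if (ok) return(cand)
  }
}

# Turn gene specs into genes/labels rows starting at a given index.
specs_to_rows <- function(specs, strain_id, contig_id, start_index,
                          locus_name = NA_character_) {
  genes <- list(); labels <- list()
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    i <- start_index + k - 1L
    id <- sprintf("%s_%04d", strain_id, i)
    product <- switch(
      s$role,
      enzyme = paste("glycoside hydrolase family",
                     paste(s$families, collapse = "/")),
      transporter = paste("carbohydrate transporter component", s$families),
      regulator = paste("transcriptional regulator", s$families),
      accessory = s$product %||% "carbohydrate metabolism enzyme",
      hypothetical = "hypothetical protein",
      background = "conserved protein of unknown function",
      "protein")
    genes[[k]] <- tibble::tibble(
      gene_id = id, contig_id = contig_id,
      start = 1L + (i - 1L) * 1000L, end = (i - 1L) * 1000L + 900L,
      strand = if (k %% 2 == 0) "-" else "+", product = product,
      locus = locus_name, role = s$role)
    labels[[k]] <- switch(
      s$role,
      enzyme = tibble::tibble(
        gene_id = id, category = sub("[0-9]+$", "", s$families),
        family = s$families, ec = s$ec, pseudo = FALSE),
      transporter = tibble::tibble(
        gene_id = id, category = "TRANSPORT_COMPONENT", family = s$families,
        ec = NA_character_, pseudo = FALSE),
      regulator = tibble::tibble(
        gene_id = id, category = "REGULATOR", family = s$families,
        ec = NA_character_, pseudo = FALSE),
      accessory = tibble::tibble(
        gene_id = id, category = "CARB_METABOLISM", family = NA_character_,
        ec = NA_character_, pseudo = FALSE),
      hypothetical = tibble::tibble(
        gene_id = id, category = "HYPOTHETICAL", family = NA_character_,
        ec = NA_character_, pseudo = FALSE),
      tibble::tibble(
        gene_id = id, category = "OTHER", family = NA_character_,
        ec = NA_character_, pseudo = FALSE))
  }
  list(genes = dplyr::bind_rows(genes), labels = dplyr::bind_rows(labels))
}

bg_specs <- function(n) {
  lapply(seq_len(n), function(i) list(role = "background",
                                      families = NA_character_,
                                      ec = NA_character_))
}

#' Generate a synthetic genome with planted gpPULs and decoys
#'
#' Planted loci realize their templates in randomized internal order and
#' are flanked by at least three consecutive non-carbohydrate genes.
#' Decoys alternate between a lone GH gene at least 11 genes from any
#' transporter component and a GH-plus-ABC-transporter cluster lacking a
#' regulator; neither can be called, by construction. Background genes are
#' OTHER/HYPOTHETICAL. Mock evidence rows pass the published filters for
#' every planted and decoy CAZyme; a configurable fraction of background
#' genes receives deliberately failing rows. Identical seed and
#' configuration give identical output.
#'
#' @param cfg A [generator_config()].
#' @param templates List of [pul_template()]s to draw from; defaults to
#'   the published compositions.
#' @param strain_id Strain identifier for the generated genome.
#' @param include_enzyme_labels When `FALSE`, CAZy labels for planted and
#'   decoy enzymes are withheld from the label table (their genes are
#'   typed OTHER) so that [call_cazymes()] must recover them from the
#'   evidence tables before detection - the full-pipeline route.
#' @return List with `genome` (a `gp_genome`), `truth` (tibble: locus
#'   name, contig, first/last rank, member gene_ids), `hmm` and `blast`
#'   evidence tables, and `decoys` (tibble of decoy gene positions).
#' @export
generate_genome <- function(cfg = generator_config(),
                            templates = table2_templates("XB6B4"),
                            strain_id = "SYN1",
                            include_enzyme_labels = TRUE) {
  set.seed(cfg$seed)
  contig <- "ctg1"
  picks <- if (cfg$n_planted_puls == 0) integer() else
    sample(length(templates), cfg$n_planted_puls, replace =
             cfg$n_planted_puls > length(templates))
  blocks <- list()  # list of list(specs, locus_name)
  add_block <- function(specs, name = NA_character_) {
    blocks[[length(blocks) + 1]] <<- list(specs = specs, name = name)
  }
  add_block(bg_specs(sample(3:6, 1)))
  for (p in picks) {
    add_block(realize_template(templates[[p]], shuffle = TRUE,
                               max_dist = 11L),
              templates[[p]]$name)
    add_block(bg_specs(sample(3:6, 1)))
  }
  # decoy section: separated from everything carbohydrate-related by a
  # long background run so lone GH decoys sit >= 11 genes from any
  # transporter component
  if (cfg$n_decoys > 0) {
    add_block(bg_specs(12L))
    for (d in seq_len(cfg$n_decoys)) {
      if (d %% 2 == 1) {
        add_block(list(list(role = "enzyme", families = "GH13",
                            ec = NA_character_)), "decoy_lone_gh")
      } else {
        add_block(c(list(list(role = "enzyme", families = "GH43",
                              ec = NA_character_)),
                    lapply(transporter_components("ABC", 3), function(f) {
                      list(role = "transporter", families = f,
                           ec = NA_character_)
                    })), "decoy_no_regulator")
      }
      add_block(bg_specs(12L))
    }
  }
  used <- sum(vapply(blocks, function(b) length(b$specs), integer(1)))
  if (used > cfg$genes_per_genome) {
    stop("infeasible packing: ", used, " genes needed but genes_per_genome = ",
         cfg$genes_per_genome)
  }
  if (used < cfg$genes_per_genome) {
    add_block(bg_specs(cfg$genes_per_genome - used))
  }

  genes <- list(); labels <- list()
  idx <- 1L
  truth_rows <- list(); decoy_rows <- list()
  for (b in blocks) {
    rows <- specs_to_rows(b$specs, strain_id, contig, idx, b$name)
    genes[[length(genes) + 1]] <- rows$genes
    labels[[length(labels) + 1]] <- rows$labels
    if (!is.na(b$name) && !startsWith(b$name, "decoy")) {
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        pul_name = b$name, contig_id = contig,
        first_rank = idx - 1L, last_rank = idx - 1L + length(b$specs) - 1L,
        gene_ids = paste(rows$genes$gene_id, collapse = ";"))
    }
    if (!is.na(b$name) && startsWith(b$name, "decoy")) {
      decoy_rows[[length(decoy_rows) + 1]] <- tibble::tibble(
        decoy_type = b$name, first_rank = idx - 1L,
        last_rank = idx - 1L + length(b$specs) - 1L,
        gene_ids = paste(rows$genes$gene_id, collapse = ";"))
    }
    idx <- idx + length(b$specs)
  }
  genes <- dplyr::bind_rows(genes)
  labels <- dplyr::bind_rows(labels)

  # mock evidence: passing rows for every CAZy-labelled gene, failing rows
  # for a fraction of background genes
  caz <- labels[labels$category %in% c("GH", "CE", "PL"), , drop = FALSE]
  hmm <- tibble::tibble(gene_id = caz$gene_id, family = caz$family,
                        evalue = 1e-20, aln_len = 150L, coverage = 0.8)
  with_ec <- caz[!is.na(caz$ec), , drop = FALSE]
  blast <- tibble::tibble(gene_id = with_ec$gene_id,
                          subject_annotation = with_ec$ec,
                          evalue = 1e-50, identity_pct = 80, bitscore = 400)
  bg_ids <- genes$gene_id[genes$role == "background"]
  n_fail <- round(cfg$evidence_fail_fraction * length(bg_ids))
  if (n_fail > 0) {
    fail_ids <- sample(bg_ids, n_fail)
    hmm <- dplyr::bind_rows(hmm, tibble::tibble(
      gene_id = fail_ids, family = "GH13", evalue = 1e-2, aln_len = 150L,
      coverage = 0.8))
    blast <- dplyr::bind_rows(blast, tibble::tibble(
      gene_id = fail_ids, subject_annotation = "3.2.1.1", evalue = 1e-6,
      identity_pct = 30, bitscore = 100))
  }

  if (!include_enzyme_labels) {
    enzyme_ids <- unique(caz$gene_id)
    labels <- labels[!labels$gene_id %in% enzyme_ids, , drop = FALSE]
    labels <- dplyr::bind_rows(labels, tibble::tibble(
      gene_id = enzyme_ids, category = "OTHER", family = NA_character_,
      ec = NA_character_, pseudo = FALSE))
  }

  genome <- new_genome(strain_id, genes[, c("gene_id", "contig_id", "start",
                                            "end", "strand", "product")],
                       labels)
  truth <- if (length(truth_rows) > 0) dplyr::bind_rows(truth_rows) else
    tibble::tibble(pul_name = character(), contig_id = character(),
                   first_rank = integer(), last_rank = integer(),
                   gene_ids = character())
  decoys <- if (length(decoy_rows) > 0) dplyr::bind_rows(decoy_rows) else
    tibble::tibble(decoy_type = character(), first_rank = integer(),
                   last_rank = integer(), gene_ids = character())
  list(genome = genome, truth = truth, hmm = hmm, blast = blast,
       decoys = decoys)
}

#' Deterministic single-genome encodings of the published locus tables
#'
#' Each published locus becomes one planted locus with its printed enzyme
#' complement, transporter systems and regulator families; loci appear in
#' table order, separated by five background genes, with five background
#' genes at each end. Internal gene order follows a fixed layout (the
#' printed enzyme order split around the first transporter system); where
#' the source drawings show a different order this is an arbitrary,
#' documented choice that does not affect detection.
#'
#' @param strain `"XB6B4"` or `"A1-86"`.
#' @return List with `genome` and `truth` as in [generate_genome()].
#' @export
fixture_table2 <- function(strain = c("XB6B4", "A1-86")) {
  strain <- match.arg(strain)
  templates <- table2_templates(strain)
  strain_id <- if (strain == "XB6B4") "RO1" else "EUR"
  contig <- "ctg1"
  genes <- list(); labels <- list(); truth_rows <- list()
  idx <- 1L
  add <- function(specs, name) {
    rows <- specs_to_rows(specs, strain_id, contig, idx, name)
    genes[[length(genes) + 1]] <<- rows$genes
    labels[[length(labels) + 1]] <<- rows$labels
    if (!is.na(name)) {
      truth_rows[[length(truth_rows) + 1]] <<- tibble::tibble(
        pul_name = name, contig_id = contig, first_rank = idx - 1L,
        last_rank = idx - 1L + length(specs) - 1L,
        gene_ids = paste(rows$genes$gene_id, collapse = ";"))
    }
    idx <<- idx + length(specs)
  }
  add(bg_specs(5L), NA_character_)
  for (tpl in templates) {
    add(realize_template(tpl, shuffle = FALSE), tpl$name)
    add(bg_specs(5L), NA_character_)
  }
  genome <- new_genome(strain_id,
                       dplyr::bind_rows(genes)[, c("gene_id", "contig_id",
                                                   "start", "end", "strand",
                                                   "product")],
                       dplyr::bind_rows(labels))
  list(genome = genome, truth = dplyr::bind_rows(truth_rows))
}

#' Synthetic strain-by-set count matrix with planted ecotype structure
#'
#' Rows fall into groups of `cfg$group_sizes`; each group owns
#' `signature_cols_per_group` columns on which its counts are shifted up
#' by `cfg$shift` over the `base_count` baseline; all entries receive
#' integer jitter in `[-jitter, jitter]` and are clipped at zero (with a
#' warning when clipping occurs).
#'
#' @param cfg A [generator_config()].
#' @return List with `matrix` (strains x columns, integer) and `labels`
#'   (named integer vector of planted group memberships).
#' @export
generate_ecotype_matrix <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  n <- sum(cfg$group_sizes)
  g <- rep(seq_along(cfg$group_sizes), cfg$group_sizes)
  need <- length(cfg$group_sizes) * cfg$signature_cols_per_group
  if (cfg$n_cols < need) stop("n_cols too small for the signature layout")
  set_names <- c("Alpha-glucans", "Fructans", "Xylans and Arabinans",
                 "Pectins", "Beta-mannans", "Type-1 Arabinogalactans",
                 "Alpha- and Beta-galactosides", "Host glycans")
  cols <- c(set_names, paste0("set", seq_len(max(0, cfg$n_cols - 8))))
  cols <- cols[seq_len(cfg$n_cols)]
  m <- matrix(cfg$base_count, n, cfg$n_cols,
              dimnames = list(sprintf("strain%02d", seq_len(n)), cols))
  for (k in seq_along(cfg$group_sizes)) {
    sig <- ((k - 1) * cfg$signature_cols_per_group + 1):
      (k * cfg$signature_cols_per_group)
    m[g == k, sig] <- m[g == k, sig] + cfg$shift
  }
  if (cfg$jitter > 0) {
    m <- m + matrix(sample(seq(-cfg$jitter, cfg$jitter), length(m),
                           replace = TRUE), n)
  }
  if (any(m < 0)) {
    warning("negative counts clipped to 0")
    m[m < 0] <- 0
  }
  storage.mode(m) <- "integer"
  list(matrix = m, labels = stats::setNames(g, rownames(m)))
}

#' Growth phenotypes of the ten assayed strains
#'
#' Boolean strain-by-substrate table transcribed from the published growth
#' experiments (microtitre plates, ten strains; the eleventh genome,
#' *E. rectale* ATCC33656, was not growth-assayed). All strains grow on
#' fructo-oligosaccharides; nobody grows on beta-mannan, xyloglucan,
#' type-2 arabinogalactan or either gastric mucin. The statement that
#' *R. hominis* A2-183 "was not unable to grow" on starch is transcribed
#' as no-growth, following the surrounding text (it is the one strain
#' unable to use either starch).
#'
#' @return Logical matrix, 10 strains x 14 substrates.
#' @export
fixture_growth_matrix <- function() {
  strains <- c("A1-86", "M104/1", "T1-815",          # E. rectale
               "A2-194", "L1-83",                    # R. inulinivorans
               "L1-82", "M50/1", "XB6B4",            # R. intestinalis
               "A2-183",                             # R. hominis
               "M72/1")                              # R. faecis
  substrates <- c("FOS", "GOS", "XOS", "amylopectin", "amylose",
                  "beta-glucan_1,3-1,4", "arabinoxylan",
                  "arabinogalactan_type1", "inulin", "beta-mannan",
                  "xyloglucan", "arabinogalactan_type2", "mucin_type2",
                  "mucin_type3")
  m <- matrix(FALSE, length(strains), length(substrates),
              dimnames = list(strains, substrates))
  m[, "FOS"] <- TRUE
  m[, "GOS"] <- TRUE
  m[c("A1-86", "L1-83", "A2-183"), "GOS"] <- FALSE
  m[, "XOS"] <- TRUE
  m[c("A2-194", "L1-83"), "XOS"] <- FALSE
  m[, c("amylopectin", "amylose")] <- TRUE
  m["A2-183", c("amylopectin", "amylose")] <- FALSE
  m[c("A1-86", "M104/1", "T1-815", "A2-194", "L1-83"), "inulin"] <- TRUE
  m[c("L1-82", "M50/1", "XB6B4", "A1-86", "T1-815", "M72/1"),
    "arabinoxylan"] <- TRUE
  m[c("L1-83", "M72/1"), "beta-glucan_1,3-1,4"] <- TRUE
  m["M72/1", "arabinogalactan_type1"] <- TRUE
  m
}

#' Locus-family presence across the eleven strains
#'
#' Cross-strain presence of selected published locus families, transcribed
#' from the comparative panels: the inulin locus Eub-3 (all *E. rectale*
#' and *R. inulinivorans* strains plus *R. faecis* M72/1, whose ABC
#' permease is frameshifted - flagged `pseudo`), the second fructan locus
#' Eub-4, the *R. intestinalis*-only pectin/xylan locus Ros-2, and the
#' GH53 arabinogalactan locus shared by *R. hominis* and *R. faecis*.
#'
#' @return Tibble with columns `pul_family`, `strain_id`, `present`,
#'   `pseudo`.
#' @export
fixture_pul_presence <- function() {
  strains <- c("A1-86", "ATCC33656", "M104/1", "T1-815",
               "A2-194", "L1-83", "L1-82", "M50/1", "XB6B4",
               "A2-183", "M72/1")
  fam <- function(name, present, pseudo = character()) {
    tibble::tibble(pul_family = name, strain_id = strains,
                   present = strains %in% present,
                   pseudo = strains %in% pseudo)
  }
  dplyr::bind_rows(
    fam("Eub-3", c("A1-86", "ATCC33656", "M104/1", "T1-815",
                   "A2-194", "L1-83", "M72/1"), pseudo = "M72/1"),
    fam("Eub-4", c("A1-86", "ATCC33656", "M104/1")),
    fam("Ros-2", c("L1-82", "M50/1", "XB6B4")),
    fam("AG1-GH53", c("A2-183", "M72/1"))
  )
}

#' Synthetic multi-strain protein sets with known orthology
#'
#' Builds `n_strains` genomes whose genes fall into planted orthologous
#' groups: core groups (all strains), variable groups (a random subset of
#' at least two strains) and unique genes. Orthologues are point-mutated
#' copies of a shared random template (about 95% identity); unique genes
#' are unrelated random sequences. With `proteins = TRUE`, protein
#' sequences are attached for alignment-based similarity; otherwise a
#' similarity table is synthesized directly from the planted truth
#' (within-group cross-strain pairs at high identity), which scales to
#' hundreds of genes per strain.
#'
#' @param n_strains,n_core,n_variable,n_unique Counts of strains, core
#'   groups, variable groups and per-strain unique genes.
#' @param seed Seed.
#' @param proteins Attach real sequences (small fixtures only).
#' @param protein_length Template length in residues.
#' @return List with `genomes` (list of `gp_genome`), `truth` (tibble:
#'   gene_id, strain_id, og_truth or NA for unique genes) and, when
#'   `proteins = FALSE`, `sims` (synthetic similarity table).
#' @export
generate_pangenome_strains <- function(n_strains = 4, n_core = 5,
                                       n_variable = 5, n_unique = 2,
                                       seed = 1, proteins = TRUE,
                                       protein_length = 120) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_seq <- function(len) paste(sample(aa, len, replace = TRUE),
                                  collapse = "")
  mutate_seq <- function(s, rate = 0.05) {
    x <- strsplit(s, "")[[1]]
    k <- max(1, round(rate * length(x)))
    pos <- sample(length(x), k)
    x[pos] <- vapply(x[pos], function(c) sample(setdiff(aa, c), 1),
                     character(1))
    paste(x, collapse = "")
  }
  strains <- sprintf("ST%02d", seq_len(n_strains))
  og_templates <- vapply(seq_len(n_core + n_variable), function(i)
    rand_seq(protein_length), character(1))
  membership <- lapply(seq_len(n_core + n_variable), function(i) {
    if (i <= n_core) return(seq_len(n_strains))
    sizes <- seq(2, max(2, n_strains - 1))
    size <- sizes[sample.int(length(sizes), 1)]
    sort(sample(n_strains, size))
  })
  genomes <- list(); truth <- list(); sims_rows <- list()
  gene_names <- vector("list", length(membership))
  for (s in seq_len(n_strains)) {
    ids <- character(); seqs <- character(); ogs <- character()
    for (i in seq_along(membership)) {
      if (!s %in% membership[[i]]) next
      id <- sprintf("%s_g%03d", strains[s], i)
      ids <- c(ids, id)
      ogs <- c(ogs, sprintf("tOG%03d", i))
      gene_names[[i]] <- c(gene_names[[i]], id)
      if (proteins) seqs <- c(seqs, mutate_seq(og_templates[i]))
    }
    for (u in seq_len(n_unique)) {
      id <- sprintf("%s_u%03d", strains[s], u)
      ids <- c(ids, id)
      ogs <- c(ogs, NA_character_)
      if (proteins) seqs <- c(seqs, rand_seq(protein_length))
    }
    genes <- tibble::tibble(
      gene_id = ids, contig_id = "ctg1",
      start = 1L + (seq_along(ids) - 1L) * 1000L,
      end = (seq_along(ids) - 1L) * 1000L + 900L,
      strand = "+", product = "protein")
    prot <- NULL
    if (proteins) {
      prot <- Biostrings::AAStringSet(seqs)
      names(prot) <- ids
    }
    genomes[[s]] <- new_genome(strains[s], genes, labels = NULL,
                               proteins = prot)
    truth[[s]] <- tibble::tibble(gene_id = ids, strain_id = strains[s],
                                 og_truth = ogs)
  }
  out <- list(genomes = genomes, truth = dplyr::bind_rows(truth))
  if (!proteins) {
    for (i in seq_along(gene_names)) {
      members <- gene_names[[i]]
      if (length(members) < 2) next
      pairs <- t(utils::combn(members, 2))
      strain_of <- sub("_.*$", "", members)
      for (r in seq_len(nrow(pairs))) {
        q <- pairs[r, 1]; subj <- pairs[r, 2]
        ident <- stats::rnorm(1, 92, 2)
        rec <- tibble::tibble(
          query_gene = c(q, subj), subject_gene = c(subj, q),
          query_strain = sub("_.*$", "", c(q, subj)),
          subject_strain = sub("_.*$", "", c(subj, q)),
          identity_pct = ident, query_cov = 0.95, evalue = 1e-50,
          bitscore = 300)
        sims_rows[[length(sims_rows) + 1]] <- rec
      }
    }
    out$sims <- if (length(sims_rows) > 0) dplyr::bind_rows(sims_rows) else
      tibble::tibble(query_gene = character(), subject_gene = character(),
                     query_strain = character(), subject_strain = character(),
                     identity_pct = numeric(), query_cov = numeric(),
                     evalue = numeric(), bitscore = numeric())
  }
  out
}
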