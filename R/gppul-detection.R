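#' Detection parameters for gpPUL scanning
#'
#' Defaults follow the published procedure: GH genes fewer than 11 genes
#' (rank difference, strand-agnostic) from a carbohydrate transporter
#' system seed a candidate locus; locus boundaries are set by three
#' adjacent genes with no carbohydrate-related annotation. Regulator genes
#' count as carbohydrate-related only when their family is in the
#' recognised regulator vocabulary.
#'
#' @param max_gh_transporter_distance Seeding distance in genes (strict
#'   `<`; set `inclusive_distance = TRUE` for `<=`).
#' @param boundary_run Number of adjacent non-carbohydrate genes that
#'   terminates a locus.
#' @param carb_categories Label categories treated as carbohydrate-related
#'   when scanning.
#' @param regulator_vocab Regulator family strings accepted as
#'   carbohydrate-associated regulators.
#' @param inclusive_distance Use `<=` instead of `<` for the seeding
#'   distance.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(max_gh_transporter_distance = 11L,
                             boundary_run = 3L,
                             carb_categories = c("GH", "CE", "PL", "CBM",
                                                 "TRANSPORT_COMPONENT",
                                                 "REGULATOR",
                                                 "CARB_METABOLISM"),
                             regulator_vocab = c("LacI", "AraC", "TetR",
                                                 "NagC", "AsrR", "HK", "RR",
                                                 "RR_AraC_CheY", "RR_LytTR",
                                                 "MCST"),
                             inclusive_distance = FALSE) {
  stopifnot(max_gh_transporter_distance > 0, boundary_run > 0)
  structure(list(max_gh_transporter_distance = as.integer(max_gh_transporter_distance),
                 boundary_run = as.integer(boundary_run),
                 carb_categories = carb_categories,
                 regulator_vocab = regulator_vocab,
                 inclusive_distance = inclusive_distance),
            class = "detection_params")
}

# Normalize a transporter component family to its system family.
transporter_system_family <- function(component_family) {
  out <- rep("other", length(component_family))
  out[grepl("^ABC", component_family)] <- "ABC"
  out[grepl("^GPH", component_family)] <- "GPH"
  out[grepl("^MFS", component_family)] <- "MFS"
  out[grepl("^PTS", component_family)] <- "PTS"
  out[is.na(component_family)] <- "other"
  out
}

#' Find carbohydrate transporter systems in a genome
#'
#' A transporter system is a maximal rank-contiguous run of genes labelled
#' TRANSPORT_COMPONENT on one contig, split wherever the normalized
#' component family (ABC/GPH/MFS/PTS) changes, so that a system's family is
#' uniform. A lone component is a system of size one.
#'
#' @param genome A `gp_genome`.
#' @return Tibble with one row per system: `system_id`, `contig_id`,
#'   `family`, `first_rank`, `last_rank`, `anchor_rank`, `member_genes`
#'   (`;`-joined), `n_members`.
#' @export
find_transporter_systems <- function(genome) {
  lab <- genome$labels
  tc <- lab[lab$category == "TRANSPORT_COMPONENT", , drop = FALSE]
  if (nrow(tc) == 0) {
    return(tibble::tibble(system_id = character(), contig_id = character(),
                          family = character(), first_rank = integer(),
                          last_rank = integer(), anchor_rank = integer(),
                          member_genes = character(), n_members = integer()))
  }
  fam_by_gene <- tapply(tc$family, tc$gene_id, function(x) x[1])
  unlabeled <- names(fam_by_gene)[is.na(fam_by_gene)]
  if (length(unlabeled) > 0) {
    warning("transporter component(s) without family, system family set to ",
            "'other': ", paste(unlabeled, collapse = ", "))
  }
  g <- genome$genes
  g <- g[g$gene_id %in% names(fam_by_gene), , drop = FALSE]
  g$sys_family <- transporter_system_family(
    unname(fam_by_gene[g$gene_id]))
  g <- g[order(g$contig_id, g$rank), , drop = FALSE]
  # split at contig change, rank gap, or family change
  new_run <- c(TRUE, g$contig_id[-1] != g$contig_id[-nrow(g)] |
                 g$rank[-1] != g$rank[-nrow(g)] + 1L |
                 g$sys_family[-1] != g$sys_family[-nrow(g)])
  run_id <- cumsum(new_run)
  systems <- lapply(split(seq_len(nrow(g)), run_id), function(idx) {
    tibble::tibble(contig_id = g$contig_id[idx[1]],
                   family = g$sys_family[idx[1]],
                   first_rank = min(g$rank[idx]),
                   last_rank = max(g$rank[idx]),
                   anchor_rank = min(g$rank[idx]),
                   member_genes = paste(g$gene_id[idx], collapse = ";"),
                   n_members = length(idx))
  })
  out <- dplyr::bind_rows(systems)
  out$system_id <- sprintf("%s_sys%02d", genome$strain_id, seq_len(nrow(out)))
  out[, c("system_id", "contig_id", "family", "first_rank", "last_rank",
          "anchor_rank", "member_genes", "n_members")]
}

# Per-gene carbohydrate-related flag in contig rank order.
carb_related_flags <- function(genome, params) {
  lab <- genome$labels
  related <- lab$category %in% setdiff(params$carb_categories, "REGULATOR")
  if ("REGULATOR" %in% params$carb_categories) {
    related <- related | (lab$category == "REGULATOR" &
                            !is.na(lab$family) &
                            lab$family %in% params$regulator_vocab)
  }
  ids <- unique(lab$gene_id[related])
  genome$genes$gene_id %in% ids
}

#' Seed candidate loci: GH genes near transporter systems
#'
#' Returns all (GH gene, transporter system) pairs on the same contig whose
#' minimum rank distance from the GH gene to any system member is below the
#' seeding threshold (strictly, by default).
#'
#' @param genome A `gp_genome` whose labels carry GH families (see
#'   [call_cazymes()]).
#' @param systems Output of [find_transporter_systems()].
#' @param params A [detection_params()] object.
#' @return Tibble with columns `gh_gene`, `system_id`, `contig_id`,
#'   `gh_rank`, `distance`.
#' @export
seed_candidates <- function(genome, systems, params = detection_params()) {
  gh_ids <- genes_with_category(genome, "GH")
  g <- genome$genes
  gh <- g[g$gene_id %in% gh_ids, , drop = FALSE]
  out <- list()
  if (nrow(gh) > 0 && nrow(systems) > 0) {
    for (i in seq_len(nrow(gh))) {
      same <- systems[systems$contig_id == gh$contig_id[i], , drop = FALSE]
      if (nrow(same) == 0) next
      # distance to nearest member of each system; members are contiguous,
      # so distance to the run is distance to its nearest end (0 inside)
      d <- pmax(same$first_rank - gh$rank[i], gh$rank[i] - same$last_rank, 0L)
      hit <- if (params$inclusive_distance) {
        d <= params$max_gh_transporter_distance
      } else {
        d < params$max_gh_transporter_distance
      }
      if (any(hit)) {
        out[[length(out) + 1]] <- tibble::tibble(
          gh_gene = gh$gene_id[i], system_id = same$system_id[hit],
          contig_id = gh$contig_id[i], gh_rank = gh$rank[i],
          distance = d[hit])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gh_gene = character(), system_id = character(),
                          contig_id = character(), gh_rank = integer(),
                          distance = integer()))
  }
  dplyr::bind_rows(out)
}

#' Extend seeds to locus boundaries and call gpPULs
#'
#' Each contig is segmented at every run of `boundary_run` or more adjacent
#' genes lacking carbohydrate-related labels; segments are trimmed so they
#' start and end on carbohydrate-related genes. Extending any seed
#' gene-by-gene in both directions until such a run is met yields exactly
#' the trimmed segment containing it, so overlapping seed extensions merge
#' by construction (merge-then-validate). A segment is emitted as a gpPUL
#' only if it contains at least one seed pair and satisfies the
#' minimum-component rule: one polysaccharide-degrading enzyme (GH/CE/PL;
#' CARB_METABOLISM genes such as xylose isomerase count as
#' carbohydrate-related for boundaries but not for this slot), one
#' transporter system and one recognised transcriptional regulator.
#'
#' @param genome A `gp_genome`.
#' @param seeds Output of [seed_candidates()]; when `NULL`, systems and
#'   seeds are computed internally.
#' @param params A [detection_params()] object.
#' @param systems Optional precomputed [find_transporter_systems()] table.
#' @return Tibble with one row per locus: `pul_id`, `strain_id`,
#'   `contig_id`, `first_rank`, `last_rank`, `start_bp`, `end_bp`,
#'   `n_genes`, `enzymes`, `enzyme_families`, `transporter_systems`,
#'   `transporter_families`, `regulators`, `regulator_families`,
#'   `accessory`, `hypothetical_members`, `member_genes` (all `;`-joined).
#' @export
extend_and_call <- function(genome, seeds = NULL, params = detection_params(),
                            systems = NULL) {
  if (is.null(systems)) systems <- find_transporter_systems(genome)
  if (is.null(seeds)) seeds <- seed_candidates(genome, systems, params)
  empty <- tibble::tibble(
    pul_id = character(), strain_id = character(), contig_id = character(),
    first_rank = integer(), last_rank = integer(), start_bp = integer(),
    end_bp = integer(), n_genes = integer(), enzymes = character(),
    enzyme_families = character(), transporter_systems = character(),
    transporter_families = character(), regulators = character(),
    regulator_families = character(), accessory = character(),
    hypothetical_members = character(), member_genes = character())
  if (nrow(seeds) == 0) return(empty)

  carb <- carb_related_flags(genome, params)
  g <- genome$genes
  lab <- genome$labels
  loci <- list()
  for (ctg in unique(seeds$contig_id)) {
    idx <- which(g$contig_id == ctg)
    idx <- idx[order(g$rank[idx])]
    flags <- carb[idx]
    segs <- carb_segments(flags, params$boundary_run)
    if (nrow(segs) == 0) next
    for (s in seq_len(nrow(segs))) {
      r0 <- g$rank[idx][segs$from[s]]
      r1 <- g$rank[idx][segs$to[s]]
      seed_in <- seeds$contig_id == ctg & seeds$gh_rank >= r0 &
        seeds$gh_rank <= r1
      # the seed's system must also intersect the segment
      if (any(seed_in)) {
        sys_rows <- systems[match(seeds$system_id[seed_in], systems$system_id), ,
                            drop = FALSE]
        seed_in[seed_in] <- sys_rows$first_rank <= r1 & sys_rows$last_rank >= r0
      }
      if (!any(seed_in)) next
      members <- g[idx, ][segs$from[s]:segs$to[s], , drop = FALSE]
      locus <- summarize_locus(genome, members, systems, params, r0, r1, ctg)
      if (!is.null(locus)) loci[[length(loci) + 1]] <- locus
    }
  }
  if (length(loci) == 0) return(empty)
  out <- dplyr::bind_rows(loci)
  out <- out[order(out$contig_id, out$first_rank), , drop = FALSE]
  out$pul_id <- sprintf("%s_pul%02d", genome$strain_id, seq_len(nrow(out)))
  out[, names(empty)]
}

# Maximal sub-segments of a logical vector containing no run of >= k FALSE,
# trimmed to start/end on TRUE.
carb_segments <- function(flags, k) {
  n <- length(flags)
  if (n == 0 || !any(flags)) {
    return(data.frame(from = integer(), to = integer()))
  }
  r <- rle(!flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  breaks <- which(r$values & r$lengths >= k)
  cut_from <- c(1L, ends[breaks] + 1L)
  cut_to <- c(starts[breaks] - 1L, n)
  segs <- data.frame(from = cut_from, to = cut_to)
  segs <- segs[segs$from <= segs$to, , drop = FALSE]
  # trim to carbohydrate-related ends
  out <- lapply(seq_len(nrow(segs)), function(i) {
    f <- segs$from[i]; t <- segs$to[i]
    sub <- flags[f:t]
    if (!any(sub)) return(NULL)
    data.frame(from = f + which(sub)[1] - 1L,
               to = f + which(sub)[length(which(sub))] - 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(from = integer(), to = integer()) else out
}

# Build the locus record; NULL if the minimum-component rule fails.
summarize_locus <- function(genome, members, systems, params, r0, r1, ctg) {
  lab <- genome$labels[genome$labels$gene_id %in% members$gene_id, ,
                       drop = FALSE]
  enz <- lab[lab$category %in% c("GH", "CE", "PL"), , drop = FALSE]
  regs <- lab[lab$category == "REGULATOR" & !is.na(lab$family) &
                lab$family %in% params$regulator_vocab, , drop = FALSE]
  sys_in <- systems[systems$contig_id == ctg & systems$first_rank <= r1 &
                      systems$last_rank >= r0, , drop = FALSE]
  if (nrow(enz) == 0 || nrow(regs) == 0 || nrow(sys_in) == 0) return(NULL)
  acc <- lab[lab$category == "CARB_METABOLISM", , drop = FALSE]
  hyp <- lab[lab$category == "HYPOTHETICAL", , drop = FALSE]
  enz_genes <- unique(enz$gene_id)
  tibble::tibble(
    pul_id = NA_character_,
    strain_id = genome$strain_id,
    contig_id = ctg,
    first_rank = r0, last_rank = r1,
    start_bp = min(members$start), end_bp = max(members$end),
    n_genes = nrow(members),
    enzymes = paste(enz_genes, collapse = ";"),
    enzyme_families = paste(
      unlist(lapply(enz_genes, function(id) {
        f <- enz$family[enz$gene_id == id]
        f <- f[!is.na(f)]
        if (length(f) == 0) "?" else paste(sort(unique(f)), collapse = "/")
      })), collapse = ";"),
    transporter_systems = paste(sys_in$system_id, collapse = ";"),
    transporter_families = paste(sys_in$family, collapse = ";"),
    regulators = paste(unique(regs$gene_id), collapse = ";"),
    regulator_families = paste(
      regs$family[!duplicated(regs$gene_id)], collapse = ";"),
    accessory = paste(unique(acc$gene_id), collapse = ";"),
    hypothetical_members = paste(unique(hyp$gene_id), collapse = ";"),
    member_genes = paste(members$gene_id, collapse = ";")
  )
}

#' Detect gpPULs in a genome (seed, extend, validate)
#'
#' Convenience wrapper running [find_transporter_systems()],
#' [seed_candidates()] and [extend_and_call()], optionally followed by
#' substrate prediction.
#'
#' @param genome A `gp_genome` with CAZyme labels present.
#' @param params A [detection_params()] object.
#' @param set_map Optional `carb_set_map`; when supplied, adds
#'   `predicted_substrates` and `confident` columns via
#'   [predict_substrates()].
#' @return The locus table from [extend_and_call()].
#' @export
detect_gppuls <- function(genome, params = detection_params(),
                          set_map = NULL) {
  systems <- find_transporter_systems(genome)
  seeds <- seed_candidates(genome, systems, params)
  puls <- extend_and_call(genome, seeds, params, systems)
  if (!is.null(set_map) && nrow(puls) > 0) {
    pred <- lapply(seq_len(nrow(puls)), function(i) {
      predict_substrates(puls[i, ], genome, set_map)
    })
    puls$predicted_substrates <- vapply(pred, function(p)
      paste(p$predicted_substrates, collapse = ";"), character(1))
    puls$confident <- vapply(pred, function(p) p$confident, logical(1))
  } else if (!is.null(set_map)) {
    puls$predicted_substrates <- character(0)
    puls$confident <- logical(0)
  }
  puls
}

#' Predict the substrate set of a gpPUL
#'
#' The prediction is the union of the carbohydrate sets of the locus's
#' member GH/CE/PL genes (family-level mapping first, per-gene EC as
#' fallback, with the type-1 arabinogalactan override). The call is
#' flagged confident when the union spans at most `max_sets` distinct sets
#' and at least `min_assigned_frac` of the member enzymes received an
#' assignment; both knobs are exposed because "reasonable confidence" is a
#' judgement call, and the raw union is always reported.
#'
#' @param pul One row of the locus table from [extend_and_call()].
#' @param genome The `gp_genome` the locus came from.
#' @param set_map A `carb_set_map`.
#' @param max_sets,min_assigned_frac Confidence rule knobs.
#' @return List with `predicted_substrates` (character vector) and
#'   `confident` (logical).
#' @export
predict_substrates <- function(pul, genome, set_map = default_carb_set_map(),
                               max_sets = 2, min_assigned_frac = 0.5) {
  enz_genes <- strsplit(pul$enzymes, ";", fixed = TRUE)[[1]]
  enz_genes <- enz_genes[enz_genes != ""]
  if (length(enz_genes) == 0) {
    return(list(predicted_substrates = character(), confident = FALSE))
  }
  lab <- genome$labels
  per_gene <- lapply(enz_genes, function(id) {
    rows <- lab[lab$gene_id == id, , drop = FALSE]
    carb_sets_for(rows$family[rows$category %in% c("GH", "CE", "PL")],
                  rows$ec, set_map)
  })
  # the type-1 arabinogalactan override is per-gene (inside
  # carb_sets_for); the locus union keeps other members' sets untouched
  sets <- unique(unlist(per_gene))
  assigned <- vapply(per_gene, function(s) length(s) > 0, logical(1))
  confident <- length(sets) >= 1 && length(sets) <= max_sets &&
    mean(assigned) >= min_assigned_frac
  list(predicted_substrates = sort(sets), confident = confident)
}

#' Compare gpPULs across strains through pan-genome orthology
#'
#' Two loci in different strains are called orthologous when at least half
#' of the smaller locus's genes share orthologous groups with genes of the
#' other locus. Locus families are connected components of the resulting
#' orthology graph; the output reports the overlap fraction behind every
#' call and a presence/absence matrix of locus families by strain.
#'
#' @param puls Named list (by strain) of locus tables from
#'   [extend_and_call()], or one combined table with a `strain_id` column.
#' @param ogs Orthologous-group membership from [bbh_cluster()] over the
#'   same gene universe.
#' @param min_overlap Minimum shared-gene fraction of the smaller locus.
#' @return List with `pairs` (tibble: pul_a, pul_b, shared, smaller,
#'   overlap, orthologous), `families` (tibble: pul_id, family_id) and
#'   `presence` (locus-family x strain logical matrix).
#' @export
compare_puls_across_strains <- function(puls, ogs, min_overlap = 0.5) {
  if (is.list(puls) && !is.data.frame(puls)) puls <- dplyr::bind_rows(puls)
  stopifnot(nrow(puls) >= 1)
  og_of <- stats::setNames(ogs$og_id, ogs$gene_id)
  pul_ogs <- lapply(seq_len(nrow(puls)), function(i) {
    genes <- strsplit(puls$member_genes[i], ";", fixed = TRUE)[[1]]
    list(genes = genes, ogs = unname(og_of[genes]))
  })
  n <- nrow(puls)
  pairs <- list()
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (puls$strain_id[i] == puls$strain_id[j]) next
        a <- pul_ogs[[i]]; b <- pul_ogs[[j]]
        # genes of the smaller locus whose OG occurs in the other locus;
        # singleton (unique) OGs can never be shared across strains
        if (length(a$genes) <= length(b$genes)) {
          small <- a; large <- b
        } else {
          small <- b; large <- a
        }
        shared <- sum(!is.na(small$ogs) & small$ogs %in% large$ogs &
                        !startsWith(small$ogs, "UNQ_"))
        overlap <- shared / length(small$genes)
        ortho <- overlap >= min_overlap
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          pul_a = puls$pul_id[i], pul_b = puls$pul_id[j],
          shared = shared, smaller = length(small$genes),
          overlap = overlap, orthologous = ortho)
        if (ortho) edges[[length(edges) + 1]] <- c(puls$pul_id[i],
                                                   puls$pul_id[j])
      }
    }
  }
  pairs <- if (length(pairs) > 0) dplyr::bind_rows(pairs) else
    tibble::tibble(pul_a = character(), pul_b = character(),
                   shared = integer(), smaller = integer(),
                   overlap = numeric(), orthologous = logical())
  g <- igraph::graph_from_data_frame(
    if (length(edges) > 0) do.call(rbind, edges) else
      matrix(character(), ncol = 2),
    directed = FALSE, vertices = data.frame(name = puls$pul_id))
  comp <- igraph::components(g)
  fam_id <- sprintf("pulfam%02d", comp$membership)
  families <- tibble::tibble(pul_id = names(comp$membership),
                             family_id = unname(fam_id))
  strain_of <- stats::setNames(puls$strain_id, puls$pul_id)
  strains <- sort(unique(puls$strain_id))
  fams <- sort(unique(families$family_id))
  presence <- matrix(FALSE, length(fams), length(strains),
                     dimnames = list(fams, strains))
  for (k in seq_len(nrow(families))) {
    presence[families$family_id[k], strain_of[families$pul_id[k]]] <- TRUE
  }
  list(pairs = pairs, families = families, presence = presence)
}

#' Write a gpPUL table as TSV, and the loci as GFF3 region features
#'
#' @param puls Locus table from [extend_and_call()] or [detect_gppuls()].
#' @param genome The source `gp_genome` (needed for the GFF3 child genes).
#' @param out_tsv,out_gff Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_gppul_tables <- function(puls, genome, out_tsv = NULL, out_gff = NULL) {
  if (!is.null(out_tsv)) {
    utils::write.table(puls, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out_gff)) {
    g <- genome$genes
    lines <- c("##gff-version 3")
    for (i in seq_len(nrow(puls))) {
      lines <- c(lines, paste(puls$contig_id[i], "gppulr", "region",
                              puls$start_bp[i], puls$end_bp[i], ".", "+", ".",
                              paste0("ID=", puls$pul_id[i]), sep = "\t"))
      members <- strsplit(puls$member_genes[i], ";", fixed = TRUE)[[1]]
      mg <- g[match(members, g$gene_id), , drop = FALSE]
      lines <- c(lines, paste(mg$contig_id, "gppulr", "CDS", mg$start, mg$end,
                              ".", mg$strand, ".",
                              paste0("ID=", mg$gene_id, ";Parent=",
                                     puls$pul_id[i]), sep = "\t"))
    }
    writeLines(lines, out_gff)
  }
  invisible(c(out_tsv, out_gff))
}
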