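#' Pairwise protein similarities across strains
#'
#' Computes global (Needleman-Wunsch) alignments for every ordered
#' cross-strain gene pair and reports identity (PID1: matches over
#' alignment length), query coverage (query residues aligned opposite
#' subject residues over query length), the raw alignment score as a
#' bit-score surrogate and a Karlin-Altschul-style surrogate e-value
#' `m * n * 2^-score`. Intended for synthetic and fixture genomes of at
#' most a few hundred genes; precomputed similarity tables in the same
#' six-column layout can be supplied to [bbh_cluster()] instead.
#'
#' @param genomes List of `gp_genome` objects carrying `proteins`
#'   ([Biostrings::AAStringSet] named by gene_id).
#' @return Tibble with columns `query_gene`, `subject_gene`,
#'   `query_strain`, `subject_strain`, `identity_pct`, `query_cov`,
#'   `evalue`, `bitscore`.
#' @export
compute_similarities <- function(genomes) {
  stopifnot(length(genomes) >= 2)
  strains <- vapply(genomes, function(g) g$strain_id, character(1))
  if (anyDuplicated(strains)) stop("duplicate strain_id among genomes")
  prot <- lapply(genomes, function(g) {
    if (is.null(g$proteins)) {
      warning("no proteins for strain ", g$strain_id, "; skipped")
      Biostrings::AAStringSet()
    } else g$proteins
  })
  names(prot) <- strains
  sub_mat <- nw_substitution_matrix()
  rows <- list()
  for (a in seq_along(strains)) {
    for (b in seq_along(strains)) {
      if (a == b) next
      pa <- prot[[a]]; pb <- prot[[b]]
      if (length(pa) == 0 || length(pb) == 0) next
      for (qi in seq_along(pa)) {
        aln <- Biostrings::pairwiseAlignment(
          rep(pa[qi], length(pb)), pb, type = "global",
          substitutionMatrix = sub_mat, gapOpening = 10, gapExtension = 0.5)
        qa <- as.character(Biostrings::alignedPattern(aln))
        sa <- as.character(Biostrings::alignedSubject(aln))
        stats_m <- alignment_stats(qa, sa, Biostrings::width(pa[qi]))
        score <- Biostrings::score(aln)
        rows[[length(rows) + 1]] <- tibble::tibble(
          query_gene = names(pa)[qi],
          subject_gene = names(pb),
          query_strain = strains[a],
          subject_strain = strains[b],
          identity_pct = stats_m$identity,
          query_cov = stats_m$coverage,
          evalue = pmin(1, as.numeric(Biostrings::width(pa[qi])) *
                          as.numeric(Biostrings::width(pb)) * 2^(-score)),
          bitscore = score
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Simple +2/-1 substitution matrix over the amino-acid alphabet; keeps the
# alignment model transparent enough to re-derive by dynamic programming.
nw_substitution_matrix <- function(match = 2, mismatch = -1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(mismatch, length(aa), length(aa), dimnames = list(aa, aa))
  diag(m) <- match
  m
}

# identity = matches / alignment length; coverage = query residues aligned
# opposite subject residues / query length
alignment_stats <- function(qa, sa, qlen) {
  qs <- strsplit(qa, "")
  ss <- strsplit(sa, "")
  identity <- numeric(length(qs))
  coverage <- numeric(length(qs))
  for (i in seq_along(qs)) {
    q <- qs[[i]]; s <- ss[[i]]
    identity[i] <- 100 * sum(q == s & q != "-") / length(q)
    coverage[i] <- sum(q != "-" & s != "-") / qlen
  }
  list(identity = identity, coverage = coverage)
}

#' Cluster genes into orthologous groups by bidirectional best hit
#'
#' Similarity records are first filtered at the published orthology
#' thresholds (identity >= 45% over >= 50% of the query, e-value < 1e-5,
#' bit score > 50). For each ordered strain pair the best hit per query is
#' chosen by bit score (ties broken by higher identity, then lexicographic
#' subject id); a BBH edge exists when best hits are reciprocal.
#' Orthologous groups are the connected components of the BBH graph (so a
#' group may span strains linked transitively); genes in no component are
#' unique singletons. Within-strain records never contribute edges.
#'
#' @param sims Similarity table as produced by [compute_similarities()]
#'   (columns `query_gene`, `subject_gene`, `query_strain`,
#'   `subject_strain`, `identity_pct`, `query_cov`, `evalue`, `bitscore`).
#' @param genomes List of `gp_genome` objects defining the gene universe.
#' @param min_identity,min_coverage,max_evalue,min_bitscore Orthology
#'   thresholds; defaults are the published values.
#' @return Tibble with columns `og_id`, `gene_id`, `strain_id`,
#'   `n_strains`, `status` (`core`/`variable`/`unique`), one row per gene.
#' @export
bbh_cluster <- function(sims, genomes, min_identity = 45, min_coverage = 0.5,
                        max_evalue = 1e-5, min_bitscore = 50) {
  universe <- dplyr::bind_rows(lapply(genomes, function(g) {
    tibble::tibble(gene_id = g$genes$gene_id, strain_id = g$strain_id)
  }))
  if (anyDuplicated(universe$gene_id)) {
    stop("gene_ids must be unique across strains")
  }
  n_total <- length(unique(universe$strain_id))

  sims <- tibble::as_tibble(sims)
  keep <- sims$identity_pct >= min_identity & sims$query_cov >= min_coverage &
    sims$evalue < max_evalue & sims$bitscore > min_bitscore &
    sims$query_strain != sims$subject_strain
  sims <- sims[keep, , drop = FALSE]

  edges <- NULL
  if (nrow(sims) > 0) {
    # deterministic best hit per (query, subject strain)
    ord <- order(sims$query_gene, sims$subject_strain, -sims$bitscore,
                 -sims$identity_pct, sims$subject_gene)
    sims <- sims[ord, , drop = FALSE]
    best <- sims[!duplicated(paste(sims$query_gene, sims$subject_strain)), ,
                 drop = FALSE]
    fwd <- paste(best$query_gene, best$subject_gene)
    rev <- paste(best$subject_gene, best$query_gene)
    reciprocal <- fwd %in% rev
    edges <- best[reciprocal, c("query_gene", "subject_gene"), drop = FALSE]
  }

  member_of <- rep(NA_integer_, nrow(universe))
  names(member_of) <- universe$gene_id
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = universe$gene_id))
    comp <- igraph::components(g)
    memb <- comp$membership  # named by gene_id
    memb[comp$csize[memb] < 2] <- NA_integer_
    member_of[names(memb)] <- memb
  }

  res <- universe
  res$component <- member_of[res$gene_id]
  clustered <- !is.na(res$component)
  comp_ids <- sort(unique(res$component[clustered]))
  og_index <- match(res$component, comp_ids)
  res$og_id <- ifelse(clustered, sprintf("OG%04d", og_index),
                      paste0("UNQ_", res$gene_id))
  ns <- tapply(res$strain_id, res$og_id, function(s) length(unique(s)))
  res$n_strains <- as.integer(ns[res$og_id])
  res$status <- ifelse(!clustered, "unique",
                       ifelse(res$n_strains == n_total, "core", "variable"))
  res$component <- NULL
  res[, c("og_id", "gene_id", "strain_id", "n_strains", "status")]
}

#' Partition a pan-genome into core, variable and unique fractions
#'
#' Core groups are present in all strains analysed, variable groups in two
#' or more but not all, unique genes in one strain only. The partition is
#' exhaustive and exclusive: every gene sits in exactly one orthologous
#' group or singleton.
#'
#' @param ogs Membership table from [bbh_cluster()].
#' @param n_strains_total Total number of strains analysed; defaults to the
#'   number of distinct strains in `ogs`.
#' @return List with `summary` (tibble: status, n_ogs, n_genes) and
#'   `per_strain` (tibble: strain_id, status, n_genes, fraction).
#' @export
partition_pangenome <- function(ogs,
                                n_strains_total = length(unique(ogs$strain_id))) {
  ogs <- tibble::as_tibble(ogs)
  og_status <- ogs[!duplicated(ogs$og_id), c("og_id", "n_strains", "status")]
  # recompute status against the stated strain total (a strain may have
  # contributed no genes to a subset table)
  og_status$status <- ifelse(og_status$status == "unique", "unique",
                             ifelse(og_status$n_strains == n_strains_total,
                                    "core", "variable"))
  ogs$status <- og_status$status[match(ogs$og_id, og_status$og_id)]
  summary <- dplyr::count(og_status, .data$status, name = "n_ogs")
  gene_counts <- dplyr::count(ogs, .data$status, name = "n_genes")
  summary <- dplyr::full_join(summary, gene_counts, by = "status")
  summary$n_ogs[is.na(summary$n_ogs)] <- 0L
  summary$n_genes[is.na(summary$n_genes)] <- 0L
  all_status <- tibble::tibble(status = c("core", "variable", "unique"))
  summary <- dplyr::left_join(all_status, summary, by = "status")
  summary$n_ogs[is.na(summary$n_ogs)] <- 0L
  summary$n_genes[is.na(summary$n_genes)] <- 0L

  per_strain <- dplyr::count(ogs, .data$strain_id, .data$status,
                             name = "n_genes")
  per_strain <- per_strain %>%
    dplyr::group_by(.data$strain_id) %>%
    dplyr::mutate(fraction = .data$n_genes / sum(.data$n_genes)) %>%
    dplyr::ungroup()
  stopifnot(sum(summary$n_genes) == nrow(ogs))
  list(summary = summary, per_strain = per_strain)
}

#' Write / read an orthologous-group membership TSV
#' @param ogs Membership table from [bbh_cluster()].
#' @param out Output path.
#' @return `out` (writer) or the membership tibble (reader).
#' @export
write_og_tsv <- function(ogs, out) {
  utils::write.table(ogs, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname write_og_tsv
#' @param path Path to a TSV written by [write_og_tsv()].
#' @export
read_og_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
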