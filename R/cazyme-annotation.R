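#' @importFrom rlang .data
NULL

#' Evidence filter thresholds for CAZyme calling
#'
#' Defaults are the published cutoffs: protein-search (blastp-style) hits
#' against the EC 3.2.1 reference are kept at E-value <= 1e-10, identity
#' >= 35% and bit score >= 200; HMM domain hits are kept at E-value <= 1e-3
#' for alignments shorter than 80 aa, <= 1e-5 for alignments of 80 aa or
#' more, and HMM coverage strictly > 0.3. Boundary semantics keep hits
#' sitting exactly on an e-value/identity/bitscore cutoff; coverage is
#' strict.
#'
#' @param blast_max_e,blast_min_identity,blast_min_bitscore Protein-search
#'   cutoffs.
#' @param hmm_max_e_short,hmm_short_len,hmm_max_e_long,hmm_min_coverage HMM
#'   cutoffs; `hmm_short_len` is the alignment length (aa) below which the
#'   short-alignment e-value applies.
#' @return A list of thresholds with class `filter_thresholds`.
#' @export
filter_thresholds <- function(blast_max_e = 1e-10, blast_min_identity = 35,
                              blast_min_bitscore = 200,
                              hmm_max_e_short = 1e-3, hmm_short_len = 80,
                              hmm_max_e_long = 1e-5, hmm_min_coverage = 0.3) {
  t <- list(blast_max_e = blast_max_e, blast_min_identity = blast_min_identity,
            blast_min_bitscore = blast_min_bitscore,
            hmm_max_e_short = hmm_max_e_short, hmm_short_len = hmm_short_len,
            hmm_max_e_long = hmm_max_e_long,
            hmm_min_coverage = hmm_min_coverage)
  if (any(vapply(t, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all thresholds must be strictly positive numbers")
  }
  structure(t, class = "filter_thresholds")
}

check_hmm_hits <- function(hits) {
  hits <- tibble::as_tibble(hits)
  req <- c("gene_id", "family", "evalue", "aln_len", "coverage")
  if (!all(req %in% names(hits))) {
    stop("HMM hit table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(hits$evalue < 0) || any(hits$aln_len <= 0)) {
    stop("HMM hits with negative e-value or non-positive alignment length")
  }
  if (any(hits$coverage < 0 | hits$coverage > 1)) {
    stop("HMM coverage outside [0,1]")
  }
  hits
}

check_blast_hits <- function(hits) {
  hits <- tibble::as_tibble(hits)
  req <- c("gene_id", "subject_annotation", "evalue", "identity_pct",
           "bitscore")
  if (!all(req %in% names(hits))) {
    stop("protein-search hit table needs columns: ",
         paste(req, collapse = ", "))
  }
  if (any(hits$evalue < 0)) stop("negative e-values in protein-search hits")
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100)) {
    stop("identity outside [0,100]")
  }
  hits
}

#' Filter HMM domain hits at the dual-length e-value rule
#'
#' Keeps exactly the hits with (aln_len < `hmm_short_len` and
#' evalue <= `hmm_max_e_short`) or (aln_len >= `hmm_short_len` and
#' evalue <= `hmm_max_e_long`), and coverage strictly greater than
#' `hmm_min_coverage`. Filtering is idempotent and its output is always a
#' subset of its input.
#'
#' @param hits Data frame with columns `gene_id`, `family`, `evalue`,
#'   `aln_len`, `coverage`.
#' @param t A [filter_thresholds()] object.
#' @return The retained rows.
#' @export
filter_hmm_hits <- function(hits, t = filter_thresholds()) {
  hits <- check_hmm_hits(hits)
  keep <- ifelse(hits$aln_len < t$hmm_short_len,
                 hits$evalue <= t$hmm_max_e_short,
                 hits$evalue <= t$hmm_max_e_long) &
    hits$coverage > t$hmm_min_coverage
  hits[keep, , drop = FALSE]
}

#' Filter protein-search hits at the identity/bitscore/e-value rule
#'
#' Keeps exactly the hits with evalue <= `blast_max_e`, identity_pct >=
#' `blast_min_identity` and bitscore >= `blast_min_bitscore`.
#'
#' @inheritParams filter_hmm_hits
#' @param hits Data frame with columns `gene_id`, `subject_annotation`,
#'   `evalue`, `identity_pct`, `bitscore`.
#' @return The retained rows.
#' @export
filter_blast_hits <- function(hits, t = filter_thresholds()) {
  hits <- check_blast_hits(hits)
  keep <- hits$evalue <= t$blast_max_e &
    hits$identity_pct >= t$blast_min_identity &
    hits$bitscore >= t$blast_min_bitscore
  hits[keep, , drop = FALSE]
}

#' Call CAZymes from combined HMM and protein-search evidence
#'
#' A gene becomes a CAZyme call when it has at least one accepted hit from
#' either evidence stream. Families come from accepted HMM hits (CBM
#' families are reported separately as binding modules, not catalytic
#' families), EC annotations from accepted protein-search hits. Each call's
#' categories (GH/CE/PL/GT/CBM) are back-annotated onto the genome's label
#' table; an EC 3.2.1.- annotation with no HMM family implies category GH.
#'
#' @param genome A `gp_genome`.
#' @param hmm HMM hit table (see [filter_hmm_hits()]); may be `NULL`.
#' @param blast Protein-search hit table (see [filter_blast_hits()]); may be
#'   `NULL`.
#' @param sp_flags Optional named logical vector: precomputed
#'   signal-peptide flags per gene_id.
#' @param t A [filter_thresholds()] object.
#' @return A list with `calls` (tibble: gene_id, families, cbms,
#'   ec_annotations as `;`-joined strings, has_signal_peptide, n_evidence)
#'   and `genome` (the input genome with CAZy labels back-annotated).
#' @export
call_cazymes <- function(genome, hmm = NULL, blast = NULL, sp_flags = NULL,
                         t = filter_thresholds()) {
  known <- genome$genes$gene_id
  drop_unknown <- function(hits, what) {
    if (is.null(hits) || nrow(hits) == 0) return(hits)
    bad <- !hits$gene_id %in% known
    if (any(bad)) {
      warning("skipping ", sum(bad), " ", what,
              " evidence row(s) for unknown gene_id(s): ",
              paste(unique(hits$gene_id[bad]), collapse = ", "))
      hits <- hits[!bad, , drop = FALSE]
    }
    hits
  }
  hmm_ok <- if (is.null(hmm)) NULL else drop_unknown(filter_hmm_hits(hmm, t), "HMM")
  blast_ok <- if (is.null(blast)) NULL else
    drop_unknown(filter_blast_hits(blast, t), "protein-search")

  ids <- union(if (is.null(hmm_ok)) character() else hmm_ok$gene_id,
               if (is.null(blast_ok)) character() else blast_ok$gene_id)
  ids <- intersect(known, ids)  # genome order
  if (length(ids) == 0) {
    calls <- tibble::tibble(gene_id = character(), families = character(),
                            cbms = character(), ec_annotations = character(),
                            has_signal_peptide = logical(),
                            n_evidence = integer())
    return(list(calls = calls, genome = genome))
  }

  per_gene <- lapply(ids, function(id) {
    fams <- if (is.null(hmm_ok)) character() else
      sort(unique(hmm_ok$family[hmm_ok$gene_id == id]))
    cbms <- fams[grepl("^CBM", fams)]
    fams <- fams[!grepl("^CBM", fams)]
    ecs <- if (is.null(blast_ok)) character() else
      sort(unique(blast_ok$subject_annotation[blast_ok$gene_id == id]))
    list(families = fams, cbms = cbms, ecs = ecs)
  })
  n_ev <- vapply(ids, function(id) {
    (if (is.null(hmm_ok)) 0L else sum(hmm_ok$gene_id == id)) +
      (if (is.null(blast_ok)) 0L else sum(blast_ok$gene_id == id))
  }, integer(1))

  calls <- tibble::tibble(
    gene_id = ids,
    families = vapply(per_gene, function(x) paste(x$families, collapse = ";"),
                      character(1)),
    cbms = vapply(per_gene, function(x) paste(x$cbms, collapse = ";"),
                  character(1)),
    ec_annotations = vapply(per_gene, function(x) paste(x$ecs, collapse = ";"),
                            character(1)),
    has_signal_peptide = if (is.null(sp_flags)) FALSE else
      unname(sp_flags[ids]) %in% TRUE,
    n_evidence = n_ev
  )

  # Back-annotate labels: one CAZy label per (gene, family); EC-only GH
  # calls get a family-less GH label carrying the EC.
  new_rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
    x <- per_gene[[i]]
    rows <- NULL
    for (fam in c(x$families, x$cbms)) {
      rows <- rbind(rows, data.frame(
        gene_id = ids[i], category = sub("[0-9]+$", "", fam), family = fam,
        ec = NA_character_, pseudo = FALSE, stringsAsFactors = FALSE))
    }
    if (length(x$families) == 0 && length(x$ecs) > 0) {
      gh_ecs <- x$ecs[grepl("^3\\.2\\.1\\.", x$ecs)]
      for (ec in gh_ecs) {
        rows <- rbind(rows, data.frame(
          gene_id = ids[i], category = "GH", family = NA_character_,
          ec = ec, pseudo = FALSE, stringsAsFactors = FALSE))
      }
    } else if (length(x$ecs) > 0) {
      # attach ECs to the gene without implying a new category
      rows$ec[1] <- x$ecs[1]
    }
    rows
  }))
  lab <- genome$labels
  if (!is.null(new_rows)) {
    # drop duplicates already present, and displace OTHER/HYPOTHETICAL
    key_old <- paste(lab$gene_id, lab$category, lab$family)
    key_new <- paste(new_rows$gene_id, new_rows$category, new_rows$family)
    new_rows <- new_rows[!key_new %in% key_old, , drop = FALSE]
    lab <- rbind(lab, new_rows)
    placeholder <- lab$category %in% c("OTHER", "HYPOTHETICAL") &
      lab$gene_id %in% ids
    lab <- lab[!placeholder, , drop = FALSE]
  }
  if (!is.null(sp_flags)) {
    sp_ids <- intersect(names(sp_flags)[sp_flags %in% TRUE], known)
    sp_new <- sp_ids[!sp_ids %in% lab$gene_id[lab$category == "SIGNAL_PEPTIDE"]]
    if (length(sp_new) > 0) {
      lab <- rbind(lab, data.frame(gene_id = sp_new,
                                   category = "SIGNAL_PEPTIDE",
                                   family = NA_character_, ec = NA_character_,
                                   pseudo = FALSE, stringsAsFactors = FALSE))
    }
  }
  genome$labels <- tibble::as_tibble(lab)
  list(calls = calls, genome = genome)
}

#' Default carbohydrate-set map
#'
#' Maps CAZy families with a single canonical substrate directly to a
#' carbohydrate set (e.g. all GH13s to alpha-glucans); families whose
#' members attack different substrates are resolved only through per-gene
#' EC annotations. Endo-1,4-beta-galactanases (GH53 or EC 3.2.1.89) are
#' assigned exclusively to "Type-1 Arabinogalactans" and never to "Xylans
#' and Arabinans", "Pectins" or "Alpha- and Beta-galactosides".
#'
#' @return A list with `family_sets` (named list family -> set),
#'   `ec_sets` (named list EC -> set), `t1ag_set` (the override set name)
#'   and `t1ag_excluded` (set names the override bars), class
#'   `carb_set_map`.
#' @export
default_carb_set_map <- function() {
  family_sets <- list(
    GH13 = "Alpha-glucans", GH31 = "Alpha-glucans", GH77 = "Alpha-glucans",
    GH15 = "Alpha-glucans",
    GH32 = "Fructans",
    GH10 = "Xylans and Arabinans", GH39 = "Xylans and Arabinans",
    GH43 = "Xylans and Arabinans", GH51 = "Xylans and Arabinans",
    GH115 = "Xylans and Arabinans", GH120 = "Xylans and Arabinans",
    GH127 = "Xylans and Arabinans", GH8 = "Xylans and Arabinans",
    GH28 = "Pectins",
    GH26 = "Beta-mannans", GH113 = "Beta-mannans", GH130 = "Beta-mannans",
    GH36 = "Alpha- and Beta-galactosides",
    GH29 = "Host glycans", GH20 = "Host glycans", GH33 = "Host glycans",
    GH38 = "Host glycans", GH85 = "Host glycans", GH125 = "Host glycans",
    GH53 = "Type-1 Arabinogalactans"
  )
  ec_sets <- list(
    `3.2.1.89` = "Type-1 Arabinogalactans",
    `3.2.1.78` = "Beta-mannans",
    `3.2.1.37` = "Xylans and Arabinans", `3.2.1.55` = "Xylans and Arabinans",
    `3.2.1.8` = "Xylans and Arabinans", `3.2.1.156` = "Xylans and Arabinans",
    `3.2.1.15` = "Pectins",
    `3.2.1.26` = "Fructans", `3.2.1.80` = "Fructans",
    `3.2.1.1` = "Alpha-glucans", `3.2.1.41` = "Alpha-glucans",
    `3.2.1.135` = "Alpha-glucans", `3.2.1.10` = "Alpha-glucans",
    `3.2.1.20` = "Alpha-glucans",
    `3.2.1.18` = "Host glycans",
    `3.2.1.22` = "Alpha- and Beta-galactosides",
    `3.2.1.23` = "Alpha- and Beta-galactosides"
  )
  structure(list(family_sets = family_sets, ec_sets = ec_sets,
                 t1ag_set = "Type-1 Arabinogalactans",
                 t1ag_excluded = c("Xylans and Arabinans", "Pectins",
                                   "Alpha- and Beta-galactosides")),
            class = "carb_set_map")
}

#' Read a carbohydrate-set map from YAML
#'
#' The YAML mirrors [default_carb_set_map()]: top-level keys `family_sets`
#' and `ec_sets` (maps to set names), optional `t1ag_set`/`t1ag_excluded`.
#'
#' @param path YAML file path.
#' @return A `carb_set_map`.
#' @export
read_carb_set_map <- function(path) {
  y <- yaml::read_yaml(path)
  d <- default_carb_set_map()
  structure(list(family_sets = y$family_sets %||% list(),
                 ec_sets = y$ec_sets %||% list(),
                 t1ag_set = y$t1ag_set %||% d$t1ag_set,
                 t1ag_excluded = y$t1ag_excluded %||% d$t1ag_excluded),
            class = "carb_set_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Carbohydrate sets for one gene given its families and ECs. Family-level
# assignment is preferred; ECs are consulted only when no family maps.
# GH53 / EC 3.2.1.89 genes get the type-1 arabinogalactan set exclusively.
carb_sets_for <- function(families, ecs, set_map) {
  families <- families[!is.na(families)]
  ecs <- ecs[!is.na(ecs)]
  sets <- as.character(unlist(set_map$family_sets[families],
                              use.names = FALSE))
  if (length(sets) == 0) {
    sets <- as.character(unlist(set_map$ec_sets[ecs], use.names = FALSE))
  }
  sets <- unique(sets)
  if ("GH53" %in% families || "3.2.1.89" %in% ecs) {
    sets <- set_map$t1ag_set
  }
  if (set_map$t1ag_set %in% sets) {
    sets <- setdiff(sets, set_map$t1ag_excluded)
  }
  sets
}

#' Assign carbohydrate sets to CAZyme calls
#'
#' @param calls The `calls` tibble from [call_cazymes()], or any data frame
#'   with `gene_id`, `families`, `ec_annotations` (`;`-joined strings).
#' @param set_map A `carb_set_map`; defaults to [default_carb_set_map()].
#' @return Named list gene_id -> character vector of set names (possibly
#'   empty). Families absent from the map are logged once per family.
#' @export
assign_carbohydrate_sets <- function(calls, set_map = default_carb_set_map()) {
  unmapped <- character()
  out <- lapply(seq_len(nrow(calls)), function(i) {
    fams <- strsplit(calls$families[i], ";", fixed = TRUE)[[1]]
    fams <- fams[fams != ""]
    ecs <- strsplit(calls$ec_annotations[i], ";", fixed = TRUE)[[1]]
    ecs <- ecs[ecs != ""]
    miss <- fams[!fams %in% names(set_map$family_sets)]
    unmapped <<- union(unmapped, miss)
    carb_sets_for(fams, ecs, set_map)
  })
  names(out) <- calls$gene_id
  if (length(unmapped) > 0) {
    message("families without a carbohydrate set: ",
            paste(sort(unmapped), collapse = ", "))
  }
  out
}
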