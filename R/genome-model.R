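#' @importFrom dplyr %>% arrange mutate filter group_by ungroup left_join bind_rows
#' @importFrom tibble tibble as_tibble
NULL

# Functional label categories understood by the pipeline.
LABEL_CATEGORIES <- c("GH", "CE", "PL", "GT", "CBM",
                      "TRANSPORT_COMPONENT", "REGULATOR", "CARB_METABOLISM",
                      "SIGNAL_PEPTIDE", "HYPOTHETICAL", "OTHER")

CAZY_CATEGORIES <- c("GH", "CE", "PL", "GT", "CBM")

#' Construct an annotated genome
#'
#' A genome is an ordered list of genes over one or more contigs, plus a
#' functional label table. Ranks (0-based gene order within each contig) are
#' assigned by ascending start coordinate; ties are broken by (start, end,
#' gene_id) so ranking is deterministic even for overlapping genes. Rank
#' difference is the gene "distance" used by the locus scanner; strand never
#' affects locus membership.
#'
#' @param strain_id Strain identifier (e.g. a locus-tag prefix owner).
#' @param genes Data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` and optionally `product`. Coordinates are 1-based
#'   inclusive.
#' @param labels Data frame with columns `gene_id`, `category`, `family`,
#'   `ec` and optionally `pseudo` (logical). One row per label; a gene may
#'   carry several.
#' @param proteins Optional [Biostrings::AAStringSet] named by gene_id.
#' @param locus_tag_prefix Optional locus-tag prefix string.
#' @return An object of class `gp_genome`: a list with elements `strain_id`,
#'   `locus_tag_prefix`, `genes` (tibble ordered by contig then rank, with a
#'   `rank` column), `labels` (tibble) and `proteins`.
#' @export
new_genome <- function(strain_id, genes, labels = NULL, proteins = NULL,
                       locus_tag_prefix = strain_id) {
  genes <- as_tibble(genes)
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  bad <- which(is.na(genes$start) | is.na(genes$end) | genes$end < genes$start |
                 genes$start < 1L)
  if (length(bad) > 0) {
    stop("malformed coordinates for gene(s) at row(s): ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in genome: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  genes <- genes %>%
    arrange(.data$contig_id, .data$start, .data$end, .data$gene_id) %>%
    group_by(.data$contig_id) %>%
    mutate(rank = seq_len(dplyr::n()) - 1L) %>%
    ungroup()

  labels <- normalize_labels(labels, genes)

  structure(
    list(strain_id = strain_id,
         locus_tag_prefix = locus_tag_prefix,
         genes = genes,
         labels = labels,
         proteins = proteins),
    class = "gp_genome"
  )
}

# Validate and complete a label table; genes without a label row default to
# HYPOTHETICAL when their product mentions "hypothetical", else OTHER.
normalize_labels <- function(labels, genes) {
  if (is.null(labels) || nrow(labels) == 0) {
    labels <- tibble(gene_id = character(), category = character(),
                     family = character(), ec = character(),
                     pseudo = logical())
  }
  labels <- as_tibble(labels)
  if (!"family" %in% names(labels)) labels$family <- NA_character_
  if (!"ec" %in% names(labels)) labels$ec <- NA_character_
  if (!"pseudo" %in% names(labels)) labels$pseudo <- FALSE
  labels$pseudo[is.na(labels$pseudo)] <- FALSE
  labels$family[!is.na(labels$family) & labels$family == ""] <- NA_character_
  labels$ec[!is.na(labels$ec) & labels$ec == ""] <- NA_character_
  unknown <- setdiff(unique(labels$category), LABEL_CATEGORIES)
  if (length(unknown) > 0) {
    stop("unknown label categories: ", paste(unknown, collapse = ", "))
  }
  cazy <- labels$category %in% CAZY_CATEGORIES
  bad_fam <- cazy & (is.na(labels$family) |
                       !grepl("^(GH|CE|PL|GT|CBM)[0-9]+$", labels$family))
  # EC-only CAZyme calls back-annotated by the caller may carry a CAZy
  # category with no family; allow those when an EC is present.
  bad_fam <- bad_fam & is.na(labels$ec)
  if (any(bad_fam)) {
    stop("CAZy label without a valid family string for gene(s): ",
         paste(unique(labels$gene_id[bad_fam]), collapse = ", "))
  }
  orphan <- setdiff(unique(labels$gene_id), genes$gene_id)
  if (length(orphan) > 0) {
    warning("dropping labels for unknown gene(s): ",
            paste(orphan, collapse = ", "))
    labels <- labels[labels$gene_id %in% genes$gene_id, , drop = FALSE]
  }
  unlabelled <- setdiff(genes$gene_id, labels$gene_id)
  if (length(unlabelled) > 0) {
    prod <- genes$product[match(unlabelled, genes$gene_id)]
    cat_default <- ifelse(!is.na(prod) & grepl("hypothetical", prod,
                                               ignore.case = TRUE),
                          "HYPOTHETICAL", "OTHER")
    labels <- bind_rows(labels,
                        tibble(gene_id = unlabelled, category = cat_default,
                               family = NA_character_, ec = NA_character_,
                               pseudo = FALSE))
  }
  labels[, c("gene_id", "category", "family", "ec", "pseudo")]
}

#' @export
print.gp_genome <- function(x, ...) {
  cat("<gp_genome> strain", x$strain_id, "-", nrow(x$genes), "genes on",
      length(unique(x$genes$contig_id)), "contig(s)\n")
  invisible(x)
}

#' Number of genes in a genome
#' @param genome A `gp_genome`.
#' @return Integer gene count.
#' @export
n_genes <- function(genome) nrow(genome$genes)

#' Read an annotated genome from GFF3 + protein FASTA + labels TSV
#'
#' CDS features are taken from the GFF3 (their `ID` attribute is the
#' gene_id), proteins from the FASTA (headers must match IDs), and
#' functional labels from an optional TSV with header
#' `gene_id  category  family  ec` (and optionally `pseudo`). Genes lacking
#' a label row are classed HYPOTHETICAL when their product contains
#' "hypothetical", otherwise OTHER.
#'
#' @param gff_path Path to a GFF3 file with CDS features.
#' @param faa_path Optional path to a protein FASTA.
#' @param labels_path Optional path to the labels TSV.
#' @param strain_id Strain identifier; defaults to the GFF file name stem.
#' @return A [new_genome()] object.
#' @export
read_genome <- function(gff_path, faa_path = NULL, labels_path = NULL,
                        strain_id = sub("\\.gff3?$", "", basename(gff_path))) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", gff_path)
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop("CDS feature(s) without ID attribute in ", gff_path)
  product <- if ("product" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$product)
  } else NA_character_
  genes <- tibble(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = product
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  proteins <- NULL
  if (!is.null(faa_path)) {
    proteins <- Biostrings::readAAStringSet(faa_path)
    names(proteins) <- sub("\\s.*$", "", names(proteins))
    absent <- setdiff(names(proteins), genes$gene_id)
    if (length(absent) > 0) {
      warning("FASTA sequence(s) absent from GFF, skipped: ",
              paste(absent, collapse = ", "))
      proteins <- proteins[setdiff(names(proteins), absent)]
    }
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE,
                                na.strings = c("NA", ""))
  }
  new_genome(strain_id, genes, labels, proteins)
}

#' Write a genome to a flat TSV (and read it back)
#'
#' One row per gene with its coordinates, rank and a `labels` column that
#' serializes all functional labels as `category:family:ec:pseudo` triples
#' joined by `;`, so a write/read cycle is the identity on every field.
#'
#' @param genome A `gp_genome`.
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
write_genome_tsv <- function(genome, out) {
  g <- genome$genes
  lab <- genome$labels
  enc <- vapply(g$gene_id, function(id) {
    rows <- lab[lab$gene_id == id, , drop = FALSE]
    paste(sprintf("%s:%s:%s:%s", rows$category,
                  ifelse(is.na(rows$family), "", rows$family),
                  ifelse(is.na(rows$ec), "", rows$ec),
                  ifelse(rows$pseudo, "1", "0")),
          collapse = ";")
  }, character(1))
  df <- data.frame(strain_id = genome$strain_id, contig_id = g$contig_id,
                   gene_id = g$gene_id, rank = g$rank, start = g$start,
                   end = g$end, strand = g$strand,
                   product = ifelse(is.na(g$product), "", g$product),
                   labels = enc, stringsAsFactors = FALSE)
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname write_genome_tsv
#' @param path Path to a TSV written by [write_genome_tsv()].
#' @export
read_genome_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  if (nrow(df) == 0) stop("empty genome table: ", path)
  labels <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    trip <- strsplit(df$labels[i], ";", fixed = TRUE)[[1]]
    parts <- strsplit(trip, ":", fixed = TRUE)
    data.frame(
      gene_id = df$gene_id[i],
      category = vapply(parts, `[`, character(1), 1),
      family = vapply(parts, function(p) if (p[2] == "") NA_character_ else p[2],
                      character(1)),
      ec = vapply(parts, function(p) if (length(p) < 3 || p[3] == "")
        NA_character_ else p[3], character(1)),
      pseudo = vapply(parts, function(p) length(p) >= 4 && p[4] == "1",
                      logical(1)),
      stringsAsFactors = FALSE)
  }))
  genes <- df[, c("gene_id", "contig_id", "start", "end", "strand", "product")]
  genes$product[genes$product == ""] <- NA_character_
  new_genome(df$strain_id[1], genes, labels)
}

#' Per-gene label lookup helpers
#'
#' `gene_categories()` returns, for each gene in rank order, the set of
#' label categories it carries; `genes_with_category()` returns the gene_ids
#' carrying a given category.
#'
#' @param genome A `gp_genome`.
#' @return For `gene_categories()`, a named list of character vectors.
#' @export
gene_categories <- function(genome) {
  split(genome$labels$category, genome$labels$gene_id)[genome$genes$gene_id]
}

#' @rdname gene_categories
#' @param category A label category string.
#' @export
genes_with_category <- function(genome, category) {
  unique(genome$labels$gene_id[genome$labels$category == category])
}
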