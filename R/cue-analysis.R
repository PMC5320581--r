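#' Build a strain-by-GH-family or strain-by-carbohydrate-set count matrix
#'
#' Counts, per strain, the genes carrying each GH family label
#' (`level = "family"`) or each carbohydrate set (`level = "carb_set"`,
#' using the family-then-EC mapping of [default_carb_set_map()]). A gene
#' assigned to several sets counts once in each; GH53 genes count only
#' under the type-1 arabinogalactan set. All-zero columns are dropped by
#' default.
#'
#' @param genomes List of `gp_genome` objects with CAZyme labels present
#'   (see [call_cazymes()]).
#' @param level `"family"` or `"carb_set"`.
#' @param set_map A `carb_set_map` (used for `level = "carb_set"`).
#' @param drop_empty Drop all-zero columns.
#' @return Integer matrix, rows = strains, columns = families or sets.
#' @export
build_matrix <- function(genomes, level = c("family", "carb_set"),
                         set_map = default_carb_set_map(),
                         drop_empty = TRUE) {
  level <- match.arg(level)
  per_strain <- lapply(genomes, function(g) {
    lab <- g$labels
    if (level == "family") {
      gh <- lab[lab$category == "GH" & !is.na(lab$family), , drop = FALSE]
      # a gene carrying two GH families (dual-family entries) counts once
      # per family
      table(gh$family[!duplicated(paste(gh$gene_id, gh$family))])
    } else {
      caz <- unique(lab$gene_id[lab$category %in% c("GH", "CE", "PL")])
      sets <- unlist(lapply(caz, function(id) {
        rows <- lab[lab$gene_id == id, , drop = FALSE]
        carb_sets_for(rows$family[rows$category %in% c("GH", "CE", "PL")],
                      rows$ec, set_map)
      }))
      table(sets)
    }
  })
  cols <- sort(unique(unlist(lapply(per_strain, names))))
  m <- matrix(0L, length(genomes), length(cols),
              dimnames = list(vapply(genomes, function(g) g$strain_id,
                                     character(1)), cols))
  for (i in seq_along(per_strain)) {
    m[i, names(per_strain[[i]])] <- as.integer(per_strain[[i]])
  }
  if (drop_empty && ncol(m) > 0) m <- m[, colSums(m) > 0, drop = FALSE]
  m
}

#' Kendall-tau distance between strain profiles
#'
#' `d(i, j) = 1 - tau_b(row_i, row_j)`, symmetric with zero diagonal and
#' range `[0, 2]`. Tau is undefined against a constant row; such entries
#' are set to the neutral distance 1 with a warning.
#'
#' @param matrix Strain-by-column count matrix (rows are strains).
#' @return A symmetric distance matrix.
#' @export
kendall_distance <- function(matrix) {
  stopifnot(ncol(matrix) >= 2)
  tau <- suppressWarnings(stats::cor(t(matrix), method = "kendall"))
  if (anyNA(tau)) {
    warning("constant row(s): Kendall tau undefined, distance set to 1")
    tau[is.na(tau)] <- 0
  }
  d <- 1 - tau
  diag(d) <- 0
  d
}

#' Spearman distance between strain profiles
#' @inheritParams kendall_distance
#' @return A symmetric distance matrix `1 - rho`.
#' @export
spearman_distance <- function(matrix) {
  stopifnot(ncol(matrix) >= 2)
  rho <- suppressWarnings(stats::cor(t(matrix), method = "spearman"))
  if (anyNA(rho)) {
    warning("constant row(s): Spearman rho undefined, distance set to 1")
    rho[is.na(rho)] <- 0
  }
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Cluster strains into carbohydrate utilization ecotypes
#'
#' Complete-linkage agglomerative clustering on the Kendall-tau (or
#' Spearman) distance. Labels are assigned by cutting at `k` clusters when
#' given, otherwise at the largest gap between consecutive merge heights.
#' Grouping significance is a PERMANOVA (permutational multivariate
#' ANOVA) on the same distance matrix with the cluster labels as the
#' factor; `significance` is `NA` for a single cluster.
#'
#' @param matrix Strain-by-column count matrix.
#' @param method `"kendall"` or `"spearman"`.
#' @param k Optional number of ecotypes.
#' @param permutations PERMANOVA permutation count.
#' @param seed Seed for the permutation test. The fixed default makes the
#'   drawn permutation stream - and hence the p-value - reproducible
#'   without touching the caller's RNG state intentions; pass `NULL` to
#'   use the current RNG state.
#' @return List of class `cue_assignment`: `assignment` (named integer
#'   vector strain -> ecotype), `n_cues`, `significance` (PERMANOVA
#'   p-value), `tree` (hclust), `newick` (dendrogram serialization),
#'   `method`, `dist`.
#' @export
cluster_cues <- function(matrix, method = c("kendall", "spearman"), k = NULL,
                         permutations = 999, seed = 42L) {
  method <- match.arg(method)
  n <- nrow(matrix)
  if (!is.null(k) && k > n) stop("k exceeds the number of strains")
  d <- if (method == "kendall") kendall_distance(matrix) else
    spearman_distance(matrix)
  tree <- stats::hclust(stats::as.dist(d), method = "complete")
  if (is.null(k)) {
    h <- tree$height
    if (length(h) <= 1) {
      k <- n
    } else {
      gaps <- diff(h)
      k <- n - which.max(gaps)  # cut just below the widest merge gap
    }
  }
  assignment <- stats::cutree(tree, k = k)
  significance <- NA_real_
  if (k > 1) {
    if (!is.null(seed)) set.seed(seed)
    df <- data.frame(cue = factor(assignment))
    fit <- vegan::adonis2(stats::as.dist(d) ~ cue, data = df,
                          permutations = permutations)
    significance <- fit$`Pr(>F)`[1]
  }
  newick <- ape::write.tree(ape::as.phylo(tree))
  structure(list(assignment = assignment, n_cues = k,
                 significance = significance, tree = tree, newick = newick,
                 method = method, dist = d),
            class = "cue_assignment")
}

#' @export
print.cue_assignment <- function(x, ...) {
  cat("<cue_assignment>", x$n_cues, "ecotypes (", x$method, "distance );",
      "PERMANOVA p =", format(x$significance), "\n")
  print(x$assignment)
  invisible(x)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical scaling: double-centering of squared distances followed by
#' eigendecomposition. Negative eigenvalues are reported as-is (no
#' correction); axes are those with positive eigenvalues, up to `n_axes`.
#'
#' @param dist A symmetric distance matrix or `dist` object.
#' @param n_axes Number of axes to return (fewer if rank is lower).
#' @return List with `coordinates` (n x k matrix), `eigenvalues` (all n),
#'   `prop_explained` (share of positive inertia per returned axis).
#' @export
pcoa_ordinate <- function(dist, n_axes = 5) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (all(d == 0)) {
    k <- min(n_axes, n - 1)
    return(list(coordinates = matrix(0, n, k,
                                     dimnames = list(rownames(d), NULL)),
                eigenvalues = rep(0, n), prop_explained = rep(0, k)))
  }
  b <- -0.5 * d^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))  # after the row sweep this completes J B J
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- eig$values > sqrt(.Machine$double.eps) * max(abs(eig$values))
  k <- min(n_axes, sum(pos))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k, k)
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = eig$values,
       prop_explained = eig$values[seq_len(k)] / sum(eig$values[pos]))
}

#' Per-ecotype carbohydrate-set enrichment
#'
#' For each ecotype and each column, a one-sided rank-sum comparison of
#' in-ecotype versus out-of-ecotype counts (enrichment direction). The
#' p-value is an exact permutation p over all assignments of strains to
#' the in-group when that enumeration is feasible (it always is at 11
#' strains), otherwise the normal-approximation Wilcoxon p. Raw p-values
#' are reported; apply [stats::p.adjust()] downstream if desired.
#'
#' @param matrix Strain-by-set count matrix.
#' @param cues A `cue_assignment` or a named vector of ecotype labels.
#' @param max_enum Largest number of in-group combinations to enumerate
#'   exactly.
#' @return Tibble with columns `cue`, `set`, `n_in`, `p`.
#' @export
enrichment_by_cue <- function(matrix, cues, max_enum = 1e5) {
  labels <- if (inherits(cues, "cue_assignment")) cues$assignment else cues
  labels <- labels[rownames(matrix)]
  if (length(unique(labels)) < 2) stop("need at least two ecotypes")
  out <- list()
  for (cue in sort(unique(labels))) {
    in_grp <- labels == cue
    for (set in colnames(matrix)) {
      x <- matrix[, set]
      p <- rank_sum_enrichment_p(x, in_grp, max_enum)
      out[[length(out) + 1]] <- tibble::tibble(
        cue = cue, set = set, n_in = sum(in_grp), p = p)
    }
  }
  dplyr::bind_rows(out)
}

# One-sided (greater) rank-sum p-value; exact by enumeration of all
# in-group subsets when feasible.
rank_sum_enrichment_p <- function(x, in_grp, max_enum = 1e5) {
  n <- length(x)
  n_in <- sum(in_grp)
  r <- rank(x)
  obs <- sum(r[in_grp])
  if (choose(n, n_in) <= max_enum) {
    combs <- utils::combn(n, n_in)
    perm <- colSums(matrix(r[combs], nrow = n_in))
    mean(perm >= obs)
  } else {
    stats::wilcox.test(x[in_grp], x[!in_grp], alternative = "greater",
                       exact = FALSE)$p.value
  }
}

#' Genotype-phenotype concordance of locus families and growth
#'
#' Crosses a locus-family presence table against a boolean growth table
#' for declared (locus family, substrate) pairs. An exception is a strain
#' possessing the locus but not growing on the substrate (or vice versa);
#' exceptions are attributed to a pseudogenized member when the presence
#' table flags one.
#'
#' @param presence Data frame with columns `pul_family`, `strain_id`,
#'   `present` (logical) and optionally `pseudo` (logical: the strain's
#'   copy carries a pseudogene).
#' @param growth Logical strain-by-substrate matrix (see
#'   [fixture_growth_matrix()]).
#' @param pairs Data frame with columns `pul_family`, `substrate`.
#' @return Tibble with one row per pair: `pul_family`, `substrate`,
#'   `n_present_growth`, `n_present_nogrowth`, `n_absent_growth`,
#'   `n_absent_nogrowth`, `exceptions` (`;`-joined strains present but not
#'   growing, each flagged `(pseudogenized)` when applicable),
#'   `reverse_exceptions` (growing without the locus).
#' @export
phenotype_concordance <- function(presence, growth, pairs) {
  presence <- tibble::as_tibble(presence)
  if (!"pseudo" %in% names(presence)) presence$pseudo <- FALSE
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    fam <- pairs$pul_family[i]
    sub <- pairs$substrate[i]
    if (!sub %in% colnames(growth)) {
      warning("substrate absent from growth table, skipped: ", sub)
      next
    }
    pres <- presence[presence$pul_family == fam, , drop = FALSE]
    strains <- intersect(rownames(growth), pres$strain_id)
    if (length(strains) == 0) {
      warning("no strains shared between presence and growth for ", fam)
      next
    }
    has <- stats::setNames(pres$present[match(strains, pres$strain_id)],
                           strains)
    pseudo <- stats::setNames(pres$pseudo[match(strains, pres$strain_id)],
                              strains)
    grows <- growth[strains, sub]
    exc <- strains[has & !grows]
    exc_lab <- ifelse(pseudo[exc], paste0(exc, " (pseudogenized)"), exc)
    rev_exc <- strains[!has & grows]
    out[[length(out) + 1]] <- tibble::tibble(
      pul_family = fam, substrate = sub,
      n_present_growth = sum(has & grows),
      n_present_nogrowth = sum(has & !grows),
      n_absent_growth = sum(!has & grows),
      n_absent_nogrowth = sum(!has & !grows),
      exceptions = paste(exc_lab, collapse = ";"),
      reverse_exceptions = paste(rev_exc, collapse = ";"))
  }
  if (length(out) == 0) {
    return(tibble::tibble(pul_family = character(), substrate = character(),
                          n_present_growth = integer(),
                          n_present_nogrowth = integer(),
                          n_absent_growth = integer(),
                          n_absent_nogrowth = integer(),
                          exceptions = character(),
                          reverse_exceptions = character()))
  }
  dplyr::bind_rows(out)
}
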