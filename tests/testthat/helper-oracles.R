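# Independent oracles, deliberately naive: each re-derives a quantity the
# package computes by a different route.

# Affine-gap (Gotoh) global alignment score; gap of length L costs
# open + ext * L, matching the package's alignment parameters.
nw_score_oracle <- function(a, b, match = 2, mismatch = -1, open = 10,
                            ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1); X <- matrix(neg, n + 1, m + 1)
  Y <- matrix(neg, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Kendall tau-b by O(n^2) pair counting with tie corrections.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tie_x) * (conc + disc + tie_y))
}

# Brute-force per-row re-check of the evidence filters.
hmm_keep_oracle <- function(row, t) {
  e_ok <- if (row$aln_len < t$hmm_short_len) row$evalue <= t$hmm_max_e_short
          else row$evalue <= t$hmm_max_e_long
  e_ok && row$coverage > t$hmm_min_coverage
}
blast_keep_oracle <- function(row, t) {
  row$evalue <= t$blast_max_e && row$identity_pct >= t$blast_min_identity &&
    row$bitscore >= t$blast_min_bitscore
}

# Brute-force BBH orthologous groups: filter, reciprocal best hits with the
# package's tie-break, then components by repeated set expansion.
bbh_oracle <- function(sims, universe, n_total) {
  s <- sims[sims$identity_pct >= 45 & sims$query_cov >= 0.5 &
              sims$evalue < 1e-5 & sims$bitscore > 50 &
              sims$query_strain != sims$subject_strain, , drop = FALSE]
  best <- list()
  for (q in unique(s$query_gene)) {
    for (st in unique(s$subject_strain[s$query_gene == q])) {
      cand <- s[s$query_gene == q & s$subject_strain == st, , drop = FALSE]
      cand <- cand[order(-cand$bitscore, -cand$identity_pct,
                         cand$subject_gene), , drop = FALSE]
      best[[paste(q, st)]] <- cand$subject_gene[1]
    }
  }
  strain_of <- setNames(universe$strain_id, universe$gene_id)
  edges <- list()
  for (k in names(best)) {
    q <- sub(" .*$", "", k)
    subj <- best[[k]]
    back <- best[[paste(subj, strain_of[q])]]
    if (!is.null(back) && back == q) {
      edges[[length(edges) + 1]] <- sort(c(q, subj))
    }
  }
  comps <- list()
  for (e in edges) {
    hit <- which(vapply(comps, function(c) any(e %in% c), logical(1)))
    if (length(hit) == 0) {
      comps[[length(comps) + 1]] <- e
    } else {
      merged <- sort(unique(c(unlist(comps[hit]), e)))
      comps <- comps[-hit]
      comps[[length(comps) + 1]] <- merged
    }
  }
  comps[vapply(comps, length, integer(1)) >= 2]
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Tiny genome constructor for detector unit tests: `spec` is a character
# vector of codes - "O" background, "H" hypothetical, "GHnn" a GH gene,
# "CEnn", "ABC" (one component), "GPH", "MFS", "REG:LacI", "XYL" (carb
# metabolism).
toy_genome <- function(spec, strain_id = "TOY", contig_id = "c1",
                       reverse = FALSE) {
  n <- length(spec)
  if (reverse) spec <- rev(spec)
  genes <- tibble::tibble(
    gene_id = sprintf("%s_%03d", strain_id, seq_len(n)),
    contig_id = contig_id,
    start = 1L + (seq_len(n) - 1L) * 100L,
    end = (seq_len(n) - 1L) * 100L + 90L,
    strand = "+", product = "protein")
  labels <- lapply(seq_len(n), function(i) {
    code <- spec[i]
    id <- genes$gene_id[i]
    if (code == "O") {
      tibble::tibble(gene_id = id, category = "OTHER", family = NA, ec = NA)
    } else if (code == "H") {
      tibble::tibble(gene_id = id, category = "HYPOTHETICAL", family = NA,
                     ec = NA)
    } else if (grepl("^(GH|CE|PL)[0-9]+$", code)) {
      tibble::tibble(gene_id = id, category = sub("[0-9]+$", "", code),
                     family = code, ec = NA)
    } else if (code %in% c("ABC", "GPH", "MFS", "PTS")) {
      fam <- if (code == "ABC") "ABC_permease" else code
      tibble::tibble(gene_id = id, category = "TRANSPORT_COMPONENT",
                     family = fam, ec = NA)
    } else if (startsWith(code, "REG:")) {
      tibble::tibble(gene_id = id, category = "REGULATOR",
                     family = sub("^REG:", "", code), ec = NA)
    } else if (code == "XYL") {
      tibble::tibble(gene_id = id, category = "CARB_METABOLISM", family = NA,
                     ec = NA)
    } else stop("unknown code ", code)
  })
  new_genome(strain_id, genes, dplyr::bind_rows(labels))
}
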