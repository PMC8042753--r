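## Expression-profile similarity of paralogs: Spearman Re across conditions,
## the Re/KS feature, and broad/specific expression breadth calls.

#' Read a gene x condition expression matrix from TSV
#'
#' Genes are rows (first column holds the identifier), conditions are columns.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames and condition colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers in expression matrix")
  m
}

#' Spearman correlation of two genes' expression profiles
#'
#' Rank correlation (average ranks for ties) over pairwise-complete
#' conditions. This is the expression-similarity component Re of a duplicate
#' pair, computed across the condition compendium.
#'
#' @param mat expression matrix (genes x conditions).
#' @param gene_a,gene_b row identifiers.
#' @return Spearman rho, or `NA` when fewer than 3 pairwise-complete
#'   conditions are available.
#' @export
spearman_re <- function(mat, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(mat)) stop("gene absent from expression matrix: ", g)
  }
  x <- mat[gene_a, ]
  y <- mat[gene_b, ]
  complete <- !is.na(x) & !is.na(y)
  if (sum(complete) < 3L) {
    return(NA_real_)
  }
  stats::cor(x[complete], y[complete], method = "spearman")
}

#' Assemble model features for duplicate pairs
#'
#' Joins KA/KS from a divergence table with Re/KS, where Re is the Spearman
#' correlation of the two genes' expression profiles. Pairs whose features are
#' undefined (KS = 0 or NA divergence, too few complete conditions) are
#' emitted on an exclusion list with a reason instead of in the feature table.
#'
#' @param divergence table from [pair_divergence()] (kept rows).
#' @param mat expression matrix.
#' @return list with `features` (data.frame `gene_a`, `gene_b`, `pair`,
#'   `label`, `ka_ks`, `re`, `ks`, `re_ks`) and `excluded` (pair + reason).
#' @export
build_features <- function(divergence, mat) {
  n <- nrow(divergence)
  re <- vapply(seq_len(n), function(i) {
    a <- divergence$gene_a[i]
    b <- divergence$gene_b[i]
    if (a %in% rownames(mat) && b %in% rownames(mat)) {
      spearman_re(mat, a, b)
    } else {
      NA_real_
    }
  }, numeric(1))
  feat <- data.frame(
    gene_a = divergence$gene_a, gene_b = divergence$gene_b,
    pair = paste(divergence$gene_a, divergence$gene_b, sep = "|"),
    label = divergence$label,
    ka_ks = divergence$ka_ks, re = re, ks = divergence$ks,
    re_ks = re / divergence$ks,
    stringsAsFactors = FALSE
  )
  undef <- is.na(feat$ka_ks) | is.na(feat$ks) | feat$ks <= 0 | is.na(feat$re)
  excluded <- data.frame(
    pair = feat$pair[undef],
    reason = ifelse(
      is.na(feat$re[undef]) & !(is.na(feat$ka_ks[undef]) | feat$ks[undef] <= 0),
      "undefined_expression", "undefined_feature"
    ),
    stringsAsFactors = FALSE
  )
  list(features = feat[!undef, , drop = FALSE], excluded = excluded)
}

#' Classify genes as broadly or specifically expressed
#'
#' A gene is "expressed" in a condition when its value is at least `tau`
#' (default: the 60th percentile of the whole matrix). Genes expressed in at
#' least `broad_frac` of conditions are broad; genes expressed in at most
#' `specific_frac` of conditions (but at least one) are specific; the rest
#' are neither. The three knobs are deliberately exposed: breadth cutoffs are
#' a modelling choice, not a community standard.
#'
#' @param mat expression matrix.
#' @param tau expression threshold; `NULL` for the matrix 60th percentile.
#' @param broad_frac minimum fraction of conditions for a broad call.
#' @param specific_frac maximum fraction of conditions for a specific call.
#' @return data.frame `gene`, `n_expressed`, `call` in
#'   \{"broad", "specific", "neither"\}, with the thresholds as attributes.
#' @export
expression_breadth <- function(mat, tau = NULL, broad_frac = 0.95,
                               specific_frac = 0.05) {
  if (is.null(tau)) tau <- stats::quantile(mat, 0.60, na.rm = TRUE, names = FALSE)
  n_cond <- ncol(mat)
  n_expr <- rowSums(mat >= tau, na.rm = TRUE)
  call <- rep("neither", nrow(mat))
  call[n_expr >= broad_frac * n_cond] <- "broad"
  call[n_expr <= specific_frac * n_cond & n_expr >= 1] <- "specific"
  structure(
    data.frame(
      gene = rownames(mat), n_expressed = n_expr, call = call,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    tau = tau, broad_frac = broad_frac, specific_frac = specific_frac
  )
}
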