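## Functional-bias analyses: shared-annotation proportions, the contingency
## and rank tests applied throughout, hypergeometric term enrichment, and the
## assembled bias report.

#' Proportion of shared annotation terms between two genes
#'
#' Default is the Jaccard index `|A n B| / |A u B|`; `method = "min"` divides
#' the intersection by the smaller set instead.
#'
#' @param set_a,set_b character vectors of term identifiers.
#' @param method `"jaccard"` or `"min"`.
#' @return fraction in `[0, 1]`, or `NA` when both sets are empty.
#' @export
shared_set_proportion <- function(set_a, set_b, method = c("jaccard", "min")) {
  method <- match.arg(method)
  set_a <- unique(set_a[!is.na(set_a) & set_a != ""])
  set_b <- unique(set_b[!is.na(set_b) & set_b != ""])
  if (length(set_a) == 0L && length(set_b) == 0L) {
    return(NA_real_)
  }
  inter <- length(intersect(set_a, set_b))
  denom <- switch(method,
    jaccard = length(union(set_a, set_b)),
    min = min(length(set_a), length(set_b))
  )
  if (denom == 0L) return(0)
  inter / denom
}

#' Chi-squared test on a 2x2 contingency table
#'
#' Pearson chi-squared with one degree of freedom; Yates continuity
#' correction is applied by default.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param yates apply the continuity correction.
#' @return list with `statistic` and `p.value`.
#' @export
chi2_2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(tab < 0) || sum(tab) == 0) stop("invalid contingency table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided. Uses the exact null distribution when the combined sample size
#' is at most `exact_max` and the data are tie-free; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @param exact_max combined-size cutoff for the exact distribution.
#' @return list with `U` (rank-sum statistic W for `x`), `p.value` and
#'   `mode` ("exact" or "approx").
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(res$statistic), p.value = res$p.value,
       mode = if (use_exact) "exact" else "approx")
}

#' Normality, location and variance tests for replicate phenotype data
#'
#' For each trait with exactly two groups (e.g. wild-type vs transgenic):
#' a one-sample Kolmogorov-Smirnov check of each group against the normal
#' distribution fitted to it, a two-tailed equal-variance Student t-test, and
#' a two-tailed variance-ratio F-test.
#'
#' @param measurements data.frame with columns `trait`, `group`, `value`;
#'   each trait must have exactly 2 groups with >= 2 replicates each.
#' @return data.frame: one row per trait with `ks_p_1`, `ks_p_2`,
#'   `t_stat`, `t_p`, `f_ratio`, `f_p` (F entries `NA` when a group variance
#'   is zero).
#' @export
phenotype_tests <- function(measurements) {
  stopifnot(all(c("trait", "group", "value") %in% names(measurements)))
  traits <- unique(measurements$trait)
  rows <- lapply(traits, function(tr) {
    sub <- measurements[measurements$trait == tr, ]
    groups <- split(sub$value, sub$group)
    if (length(groups) != 2L) stop("trait '", tr, "' does not have exactly 2 groups")
    if (any(lengths(groups) < 2L)) stop("trait '", tr, "' has a group with < 2 replicates")
    g1 <- groups[[1]]
    g2 <- groups[[2]]
    ks_p <- vapply(list(g1, g2), function(g) {
      if (stats::sd(g) == 0) return(NA_real_)
      suppressWarnings(stats::ks.test(g, "pnorm", mean(g), stats::sd(g))$p.value)
    }, numeric(1))
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    ft <- if (stats::var(g1) == 0 || stats::var(g2) == 0) {
      list(estimate = NA_real_, p.value = NA_real_)
    } else {
      stats::var.test(g1, g2)
    }
    data.frame(
      trait = tr, group_1 = names(groups)[1], group_2 = names(groups)[2],
      ks_p_1 = ks_p[1], ks_p_2 = ks_p[2],
      t_stat = unname(tt$statistic), t_p = tt$p.value,
      f_ratio = unname(ft$estimate), f_p = ft$p.value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Term enrichment in a foreground gene set
#'
#' One-sided hypergeometric test per term (foreground draws from the
#' background universe), Benjamini-Hochberg adjusted; a term is enriched when
#' its FDR is below `alpha` and its fold enrichment exceeds 1.
#'
#' @param foreground character vector of genes (subset of `background`).
#' @param background character vector: the gene universe.
#' @param term_map data.frame with columns `gene`, `term` (one row per
#'   assignment).
#' @param alpha FDR cutoff.
#' @return data.frame `term`, `fg_count`, `bg_count`, `fold`, `p`, `fdr`,
#'   `enriched`, ordered by `p`.
#' @export
enrich_terms <- function(foreground, background, term_map, alpha = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground genes must be a subset of the background")
  }
  if (length(foreground) == 0L) {
    return(data.frame(term = character(), fg_count = integer(),
                      bg_count = integer(), fold = numeric(), p = numeric(),
                      fdr = numeric(), enriched = logical()))
  }
  term_map <- unique(term_map[term_map$gene %in% background, c("gene", "term")])
  terms <- split(term_map$gene, term_map$term)
  n_fg <- length(foreground)
  n_bg <- length(background)
  rows <- lapply(names(terms), function(tm) {
    genes <- terms[[tm]]
    k <- sum(foreground %in% genes)
    m <- length(genes)
    p <- stats::phyper(k - 1, m, n_bg - m, n_fg, lower.tail = FALSE)
    fold <- (k / n_fg) / (m / n_bg)
    data.frame(term = tm, fg_count = k, bg_count = m, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$fdr < alpha & out$fold > 1
  out[order(out$p), , drop = FALSE]
}

#' Read a gene annotation table
#'
#' TSV columns: `gene`, `go` and `domains` (semicolon-separated term lists),
#' `ppi_degree`, `core` (0/1), `mechanism` (`tandem` / `wgd` / `other`).
#'
#' @param path TSV path.
#' @return data.frame with list-columns `go_set` and `domain_set`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$go_set <- strsplit(ifelse(is.na(df$go), "", df$go), ";")
  df$domain_set <- strsplit(ifelse(is.na(df$domains), "", df$domains), ";")
  if (!all(df$mechanism %in% c("tandem", "wgd", "other"))) {
    stop("mechanism must be one of tandem, wgd, other")
  }
  df
}

#' Functional-bias report for classified duplicate pairs
#'
#' Assembles the downstream bias analyses for pairs called high vs low
#' diversified: shared-GO and shared-domain proportions (Wilcoxon), core-gene
#' proportions (chi-squared), PPI-degree comparison (Wilcoxon), broad/specific
#' expression contingency (chi-squared), and the tandem/WGD mechanism ratio
#' (chi-squared).
#'
#' @param calls classification table (`pair`, `call`) joined to gene pairs via
#'   a `pairs` data.frame with `gene_a`, `gene_b`, `pair`.
#' @param pairs data.frame mapping pair ids to `gene_a`, `gene_b` and
#'   `mechanism`.
#' @param annotations from [read_annotations()].
#' @param breadth optional breadth table from [expression_breadth()].
#' @return list of result blocks; genes without annotation are counted in
#'   `n_skipped`.
#' @export
bias_report <- function(calls, pairs, annotations, breadth = NULL) {
  dat <- merge(calls, pairs, by = "pair")
  dat <- dat[dat$call %in% c("high", "low"), , drop = FALSE]
  ann_idx_a <- match(dat$gene_a, annotations$gene)
  ann_idx_b <- match(dat$gene_b, annotations$gene)
  n_skipped <- sum(is.na(ann_idx_a) | is.na(ann_idx_b))
  ok <- !is.na(ann_idx_a) & !is.na(ann_idx_b)
  dat <- dat[ok, , drop = FALSE]
  ia <- ann_idx_a[ok]
  ib <- ann_idx_b[ok]
  hi <- dat$call == "high"

  report <- list(n_pairs = nrow(dat), n_skipped = n_skipped)
  if (nrow(dat) == 0L) {
    return(report)
  }

  ## shared-annotation proportions per pair, compared between classes
  shared_go <- mapply(function(i, j) {
    shared_set_proportion(annotations$go_set[[i]], annotations$go_set[[j]])
  }, ia, ib)
  shared_fd <- mapply(function(i, j) {
    shared_set_proportion(annotations$domain_set[[i]], annotations$domain_set[[j]])
  }, ia, ib)
  cmp_sets <- function(v) {
    a <- v[hi & !is.na(v)]
    b <- v[!hi & !is.na(v)]
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    w <- wilcoxon_rank_sum(a, b)
    list(mean_high = mean(a), mean_low = mean(b), p = w$p.value)
  }
  report$shared_go <- cmp_sets(shared_go)
  report$shared_fd <- cmp_sets(shared_fd)

  ## core-gene proportion by class (gene-level)
  gene_tab <- data.frame(
    gene = c(dat$gene_a, dat$gene_b), call = rep(dat$call, 2),
    stringsAsFactors = FALSE
  )
  gene_tab <- gene_tab[!duplicated(gene_tab$gene), , drop = FALSE]
  g_idx <- match(gene_tab$gene, annotations$gene)
  core <- annotations$core[g_idx] == 1
  core_tab <- table(factor(gene_tab$call, c("high", "low")),
                    factor(core, c(TRUE, FALSE)))
  report$core <- list(
    prop_high = mean(core[gene_tab$call == "high"]),
    prop_low = mean(core[gene_tab$call == "low"]),
    table = unclass(core_tab),
    p = tryCatch(chi2_2x2(core_tab)$p.value, error = function(e) NA_real_)
  )

  ## PPI degree by class (gene-level)
  ppi <- annotations$ppi_degree[g_idx]
  if (all(c("high", "low") %in% gene_tab$call)) {
    w <- wilcoxon_rank_sum(ppi[gene_tab$call == "low"], ppi[gene_tab$call == "high"])
    report$ppi <- list(
      median_high = stats::median(ppi[gene_tab$call == "high"]),
      median_low = stats::median(ppi[gene_tab$call == "low"]),
      p = w$p.value
    )
  }

  ## breadth contingency: class ratio among specific vs broad genes
  if (!is.null(breadth)) {
    b_call <- breadth$call[match(gene_tab$gene, breadth$gene)]
    tab <- table(factor(gene_tab$call, c("high", "low")),
                 factor(b_call, c("specific", "broad")))
    report$breadth <- list(
      table = unclass(tab),
      p = tryCatch(chi2_2x2(tab)$p.value, error = function(e) NA_real_)
    )
  }

  ## tandem/WGD mechanism ratio by class (pair-level)
  if ("mechanism" %in% names(dat)) {
    mech <- dat$mechanism
    keep <- mech %in% c("tandem", "wgd")
    tab <- table(factor(dat$call[keep], c("high", "low")),
                 factor(mech[keep], c("tandem", "wgd")))
    report$mechanism <- list(
      table = unclass(tab),
      ratio_high = tab["high", "tandem"] / tab["high", "wgd"],
      ratio_low = tab["low", "tandem"] / tab["low", "wgd"],
      p = tryCatch(chi2_2x2(tab)$p.value, error = function(e) NA_real_)
    )
  }
  report
}
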