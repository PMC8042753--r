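## Ortholog retention and branch-specific selection in the three-taxon system
## A. thaliana (At) / A. lyrata (Al) / B. rapa (Br). AS1 denotes the (At, Al)
## ancestor and AS2 the three-species ancestor; the analysed branches are
## AS1 -> Al and AS2 -> Br.

#' Read an ortholog triplet table
#'
#' TSV columns: `at_gene`, `al_gene`, `br_gene` (`"-"` when the ortholog is
#' absent), `class` (`high`/`low`), `mechanism` (`tandem`/`wgd`).
#'
#' @param path TSV path.
#' @return data.frame with `NA` for absent orthologs.
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$al_gene[df$al_gene == "-"] <- NA_character_
  df$br_gene[df$br_gene == "-"] <- NA_character_
  df
}

#' Ortholog retention rates by diversification class and mechanism
#'
#' Retention in a species is the fraction of duplicate genes with a present
#' ortholog. Rates are stratified by class, by duplication mechanism, and by
#' class within mechanism; each stratified comparison is tested with a 2x2
#' chi-squared test. Empty strata are omitted with a note.
#'
#' @param triplets data.frame from [read_triplets()].
#' @return data.frame with one row per (species, stratum, group):
#'   `species`, `stratum`, `group`, `n`, `retained`, `rate`, `p` (the
#'   chi-squared p of the two-group comparison within the stratum, repeated on
#'   both rows), plus a `notes` attribute for omitted strata.
#' @export
retention_analysis <- function(triplets) {
  rows <- list()
  notes <- character(0)
  for (sp in c("al", "br")) {
    present <- !is.na(triplets[[paste0(sp, "_gene")]])
    strata <- list(
      class = list(split = triplets$class, groups = c("low", "high")),
      mechanism = list(split = triplets$mechanism, groups = c("wgd", "tandem"))
    )
    for (mech in c("wgd", "tandem")) {
      strata[[paste0("class_within_", mech)]] <- list(
        split = ifelse(triplets$mechanism == mech, triplets$class, NA),
        groups = c("low", "high")
      )
    }
    for (st in names(strata)) {
      sdef <- strata[[st]]
      counts <- lapply(sdef$groups, function(g) {
        sel <- !is.na(sdef$split) & sdef$split == g
        c(n = sum(sel), retained = sum(present[sel]))
      })
      if (any(vapply(counts, function(x) x["n"] == 0, logical(1)))) {
        notes <- c(notes, sprintf("%s/%s: empty stratum omitted", sp, st))
        next
      }
      tab <- rbind(
        c(counts[[1]]["retained"], counts[[1]]["n"] - counts[[1]]["retained"]),
        c(counts[[2]]["retained"], counts[[2]]["n"] - counts[[2]]["retained"])
      )
      p <- tryCatch(chi2_2x2(tab)$p.value, error = function(e) NA_real_)
      for (k in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, stratum = st, group = sdef$groups[k],
          n = unname(counts[[k]]["n"]), retained = unname(counts[[k]]["retained"]),
          rate = unname(counts[[k]]["retained"] / counts[[k]]["n"]), p = p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(do.call(rbind, rows), notes = notes)
}

#' NG86 divergence directly from two coding sequences
#'
#' Convenience wrapper: strips terminal stops, translates, globally aligns
#' the proteins, back-translates and runs [ng86_ka_ks()]. With
#' `aligned = TRUE` (equal-length CDS already in codon correspondence, e.g.
#' from a pre-computed codon alignment or an indel-free simulation) the
#' protein-alignment step is skipped.
#'
#' @param cds_a,cds_b coding sequences (ACGT, frame 1, no internal stops).
#' @param aligned skip protein alignment and pair codons positionally.
#' @return a `divergence_estimate` (see [ng86_ka_ks()]).
#' @export
estimate_pair_divergence <- function(cds_a, cds_b, aligned = FALSE) {
  strip <- function(cds) sub("(TAA|TAG|TGA)$", "", toupper(cds))
  cds_a <- strip(cds_a)
  cds_b <- strip(cds_b)
  if (aligned && nchar(cds_a) == nchar(cds_b)) {
    return(ng86_ka_ks(codon_alignment_from_cds(cds_a, cds_b)))
  }
  prot <- function(cds) {
    aa <- translate_codons(substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3)))
    if (any(aa == "*")) stop("internal stop codon in CDS")
    paste(aa, collapse = "")
  }
  aln <- align_pair(prot(cds_a), prot(cds_b))
  ng86_ka_ks(backtranslate(aln, cds_a, cds_b))
}

#' Branch-specific KA and KS for an ortholog triplet
#'
#' Decomposes the three pairwise NG86 distances on the unrooted three-taxon
#' star, separately for KA and KS: the terminal branch to Al (from AS1) is
#' `(d(At,Al) + d(Al,Br) - d(At,Br)) / 2`, and the branch to Br (from AS2) is
#' `(d(At,Br) + d(Al,Br) - d(At,Al)) / 2`. Negative decompositions are
#' truncated to 0 and flagged. Difference counts are allocated to each branch
#' by scaling the tip pair's NG86 counts by the branch-to-pairwise distance
#' ratio (rounded half-up) for use in the selection test.
#'
#' @param cds_at,cds_al,cds_br coding sequences of the three orthologs.
#' @param aligned set `TRUE` when the three CDS are equal-length and already
#'   in codon correspondence (e.g. exported from an indel-free simulation or
#'   a pre-computed codon alignment); skips the protein-alignment step.
#' @return list of two `branch_estimate` objects (`al`, `br`), each with
#'   `branch`, `Ka`, `Ks`, `ka_ks`, allocated `Sd`, `Nd`, `S`, `N`, and a
#'   `truncated` flag; or `NULL` (with a warning) when a pairwise estimate is
#'   undefined.
#' @export
branch_ka_ks <- function(cds_at, cds_al, cds_br, aligned = FALSE) {
  est <- tryCatch(
    list(
      at_al = estimate_pair_divergence(cds_at, cds_al, aligned = aligned),
      at_br = estimate_pair_divergence(cds_at, cds_br, aligned = aligned),
      al_br = estimate_pair_divergence(cds_al, cds_br, aligned = aligned)
    ),
    error = function(e) NULL
  )
  if (is.null(est) ||
      any(vapply(est, function(e) is.na(e$Ka) || is.na(e$Ks), logical(1)))) {
    warning("undefined pairwise estimate; branches undetermined", call. = FALSE)
    return(NULL)
  }
  decompose <- function(what) {
    d_tal <- est$at_al[[what]]
    d_tbr <- est$at_br[[what]]
    d_lbr <- est$al_br[[what]]
    c(al = (d_tal + d_lbr - d_tbr) / 2, br = (d_tbr + d_lbr - d_tal) / 2)
  }
  b_ka <- decompose("Ka")
  b_ks <- decompose("Ks")
  half_up <- function(x) floor(x + 0.5)
  make_branch <- function(tip) {
    pair <- if (tip == "al") est$at_al else est$at_br
    trunc <- b_ka[tip] < 0 || b_ks[tip] < 0
    ka <- max(b_ka[tip], 0)
    ks <- max(b_ks[tip], 0)
    frac_s <- if (pair$Ks > 0) ks / pair$Ks else 0
    frac_n <- if (pair$Ka > 0) ka / pair$Ka else 0
    structure(
      list(
        branch = if (tip == "al") "AS1->Al" else "AS2->Br",
        Ka = unname(ka), Ks = unname(ks),
        ka_ks = if (ks > 0) unname(ka / ks) else NA_real_,
        Sd = half_up(pair$Sd * frac_s), Nd = half_up(pair$Nd * frac_n),
        S = pair$S, N = pair$N,
        truncated = unname(trunc)
      ),
      class = "branch_estimate"
    )
  }
  list(al = make_branch("al"), br = make_branch("br"))
}

#' Positive / purifying selection call for a branch
#'
#' Two-sided Fisher exact test on the 2x2 table of branch-allocated
#' (nonsynonymous, synonymous) difference counts against (nonsynonymous,
#' synonymous) site counts. The call is `positive` when `p < alpha` and
#' KA/KS > 1, `purifying` when `p < alpha` and KA/KS < 1, `neutral`
#' otherwise, and `undetermined` when branch KA/KS is undefined.
#'
#' @param branch a `branch_estimate` from [branch_ka_ks()].
#' @param alpha significance level.
#' @return list with `call`, `p.value`, and `flag` (`"no_differences"` when
#'   the branch carries no substitutions).
#' @export
selection_call <- function(branch, alpha = 0.05) {
  if (is.null(branch)) {
    return(list(call = "undetermined", p.value = NA_real_, flag = NA_character_))
  }
  if (branch$Nd + branch$Sd == 0) {
    return(list(call = "neutral", p.value = NA_real_, flag = "no_differences"))
  }
  if (is.na(branch$ka_ks)) {
    return(list(call = "undetermined", p.value = NA_real_, flag = NA_character_))
  }
  tab <- matrix(
    c(branch$Nd, branch$Sd, round(branch$N), round(branch$S)),
    nrow = 2, byrow = TRUE
  )
  p <- stats::fisher.test(tab)$p.value
  call <- if (p < alpha && branch$ka_ks > 1) {
    "positive"
  } else if (p < alpha && branch$ka_ks < 1) {
    "purifying"
  } else {
    "neutral"
  }
  list(call = call, p.value = p, flag = NA_character_)
}

#' Branch analysis over a triplet table
#'
#' Runs [branch_ka_ks()] and [selection_call()] for every triplet with all
#' three sequences, producing the per-branch table used by
#' [selection_proportions()].
#'
#' @param triplets triplet table (rows lacking an ortholog are skipped).
#' @param seqs named character vectors of CDS per species:
#'   `list(at = ..., al = ..., br = ...)`.
#' @param alpha significance level for selection calls.
#' @param aligned passed to [branch_ka_ks()]: triplet CDS are already in
#'   codon correspondence.
#' @return data.frame: `at_gene`, `class`, `mechanism`, `branch`, `ka`,
#'   `ks`, `ka_ks`, `p`, `call`.
#' @export
triplet_branch_analysis <- function(triplets, seqs, alpha = 0.05,
                                    aligned = FALSE) {
  full <- !is.na(triplets$al_gene) & !is.na(triplets$br_gene)
  rows <- list()
  for (i in which(full)) {
    br_est <- suppressWarnings(branch_ka_ks(
      seqs$at[[triplets$at_gene[i]]],
      seqs$al[[triplets$al_gene[i]]],
      seqs$br[[triplets$br_gene[i]]],
      aligned = aligned
    ))
    for (tip in c("al", "br")) {
      est <- br_est[[tip]]
      sel <- selection_call(est, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        at_gene = triplets$at_gene[i],
        class = triplets$class[i], mechanism = triplets$mechanism[i],
        branch = if (is.null(est)) c(al = "AS1->Al", br = "AS2->Br")[[tip]] else est$branch,
        ka = if (is.null(est)) NA_real_ else est$Ka,
        ks = if (is.null(est)) NA_real_ else est$Ks,
        ka_ks = if (is.null(est)) NA_real_ else est$ka_ks,
        p = sel$p.value, call = sel$call,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Selection-call proportions by class and mechanism
#'
#' Per branch and class x mechanism group: the proportion of branches under
#' positive and under purifying selection, a chi-squared comparison of each
#' group's positive-selection count against the all-branches average, and,
#' when singleton controls are supplied, a two-sided Wilcoxon of the group's
#' branch KA/KS against the singleton KA/KS distribution.
#'
#' @param branch_table output of [triplet_branch_analysis()].
#' @param singletons optional data.frame `branch`, `ka_ks` for singleton
#'   (one-to-one ortholog) control genes.
#' @return data.frame with one row per branch x class x mechanism group.
#' @export
selection_proportions <- function(branch_table, singletons = NULL) {
  bt <- branch_table[!is.na(branch_table$call), , drop = FALSE]
  rows <- list()
  for (br in unique(bt$branch)) {
    sub_br <- bt[bt$branch == br, , drop = FALSE]
    overall_pos <- mean(sub_br$call == "positive")
    groups <- split(
      sub_br,
      list(class = sub_br$class, mechanism = sub_br$mechanism),
      drop = TRUE
    )
    for (g in names(groups)) {
      sub <- groups[[g]]
      n_pos <- sum(sub$call == "positive")
      n_pur <- sum(sub$call == "purifying")
      rest <- sub_br[!(sub_br$class == sub$class[1] &
                         sub_br$mechanism == sub$mechanism[1]), , drop = FALSE]
      p_vs_avg <- if (nrow(rest) > 0) {
        tab <- rbind(
          c(n_pos, nrow(sub) - n_pos),
          c(sum(rest$call == "positive"), sum(rest$call != "positive"))
        )
        tryCatch(chi2_2x2(tab)$p.value, error = function(e) NA_real_)
      } else {
        NA_real_
      }
      p_singleton <- NA_real_
      if (!is.null(singletons)) {
        ctrl <- singletons$ka_ks[singletons$branch == br]
        vals <- sub$ka_ks[!is.na(sub$ka_ks)]
        if (length(ctrl) > 0 && length(vals) > 0) {
          p_singleton <- wilcoxon_rank_sum(vals, ctrl)$p.value
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        branch = br, class = sub$class[1], mechanism = sub$mechanism[1],
        n = nrow(sub), prop_positive = n_pos / nrow(sub),
        prop_purifying = n_pur / nrow(sub),
        overall_prop_positive = overall_pos,
        p_vs_average = p_vs_avg, p_vs_singletons = p_singleton,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Bootstrap support for an observed trend
#'
#' Resamples the rows of `data` with replacement `n_boot` times and reports
#' the fraction of resamples on which `predicate` (a function of the
#' resampled data.frame returning TRUE/FALSE) holds; non-evaluable resamples
#' count as not supporting.
#'
#' @param data data.frame of analysis units (e.g. triplets or branch rows).
#' @param predicate function `data.frame -> logical(1)`.
#' @param n_boot number of resamples.
#' @param seed RNG seed.
#' @return support fraction in `[0, 1]`.
#' @export
bootstrap_support <- function(data, predicate, n_boot = 100, seed = 1L) {
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_boot)) {
    res <- data[sample(nrow(data), replace = TRUE), , drop = FALSE]
    ok <- tryCatch(isTRUE(predicate(res)), error = function(e) FALSE)
    if (ok) hits <- hits + 1L
  }
  hits / n_boot
}
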