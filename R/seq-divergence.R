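## Sequence handling: FASTA I/O, representative records, pairwise protein
## alignment, back-translation to codons, and pair-level filtering.

#' Read CDS and protein FASTA files into gene records
#'
#' Builds one record per gene from matched CDS and protein FASTA files.
#' Identifiers are parsed from the header up to the first whitespace and
#' sequences are uppercased. A terminal stop codon (TAA/TAG/TGA) on the CDS is
#' stripped. Each record must satisfy `nchar(cds) == 3 * nchar(protein)`; the
#' protein is the representative (longest) isoform product of the CDS.
#'
#' @param cds_path path to a nucleotide FASTA of coding sequences.
#' @param pep_path path to the matching amino-acid FASTA. Only genes present
#'   in both files are returned.
#' @return a data.frame with columns `gene_id`, `cds`, `protein`.
#' @export
read_gene_records <- function(cds_path, pep_path) {
  cds_set <- Biostrings::readDNAStringSet(cds_path)
  pep_set <- Biostrings::readAAStringSet(pep_path)
  names(cds_set) <- sub("\\s.*$", "", names(cds_set))
  names(pep_set) <- sub("\\s.*$", "", names(pep_set))
  common <- intersect(names(cds_set), names(pep_set))
  if (length(common) == 0L) {
    stop("no gene identifiers shared between CDS and protein FASTA files")
  }
  cds <- toupper(as.character(cds_set[common]))
  pep <- toupper(as.character(pep_set[common]))
  pep <- sub("\\*$", "", pep)

  ## strip terminal stop codon where present
  has_stop <- nchar(cds) %% 3 == 0 &
    substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA") &
    nchar(cds) == 3L * nchar(pep) + 3L
  cds[has_stop] <- substr(cds[has_stop], 1L, nchar(cds[has_stop]) - 3L)

  bad <- nchar(cds) != 3L * nchar(pep)
  if (any(bad)) {
    stop(
      "CDS/protein length mismatch for gene(s): ",
      paste(common[bad], collapse = ", ")
    )
  }
  data.frame(
    gene_id = common, cds = unname(cds), protein = unname(pep),
    stringsAsFactors = FALSE
  )
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch global alignment with the BLOSUM62 substitution matrix and
#' affine gap penalties (via [Biostrings::pairwiseAlignment()]). Alternatively,
#' pre-aligned gapped rows (e.g. from an external aligner) can be supplied and
#' are accepted verbatim.
#'
#' @param a,b unaligned amino-acid strings, or gapped rows when
#'   `aligned = TRUE`.
#' @param aligned if `TRUE`, `a` and `b` are equal-length gapped rows imported
#'   as-is.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return an object of class `protein_alignment` with elements `row_a`,
#'   `row_b`, `identity` and `coverage` (see [identity_coverage()]).
#' @export
align_pair <- function(a, b, aligned = FALSE, gap_opening = 10, gap_extension = 0.5) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty protein sequence")
  if (aligned) {
    if (nchar(a) != nchar(b)) stop("imported alignment rows differ in length")
    both_gap <- substring(a, 1:nchar(a), 1:nchar(a)) == "-" &
      substring(b, 1:nchar(b), 1:nchar(b)) == "-"
    if (any(both_gap)) stop("imported alignment has gap-in-both columns")
    aln <- list(row_a = toupper(a), row_b = toupper(b))
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
      substitutionMatrix = blosum62(),
      gapOpening = gap_opening, gapExtension = gap_extension,
      type = "global"
    )
    aln <- list(
      row_a = as.character(Biostrings::alignedPattern(pa)),
      row_b = as.character(Biostrings::alignedSubject(pa))
    )
  }
  ic <- identity_coverage(aln)
  structure(
    c(aln, list(identity = ic[["identity"]], coverage = ic[["coverage"]])),
    class = "protein_alignment"
  )
}

blosum62 <- function() {
  if (is.null(.dd_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    ## unknown residues score 0 rather than the matrix's penalty
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .dd_cache$blosum62 <- m
  }
  .dd_cache$blosum62
}

#' Sequence identity and coverage of a pairwise protein alignment
#'
#' Identity is the fraction of identical residues among columns where both
#' rows are non-gap; coverage is the number of dually aligned columns divided
#' by the length of the longer unaligned sequence.
#'
#' @param aln a `protein_alignment` or a list with `row_a`, `row_b`.
#' @return named numeric vector `c(identity =, coverage =)`.
#' @export
identity_coverage <- function(aln) {
  ra <- strsplit(aln$row_a, "")[[1]]
  rb <- strsplit(aln$row_b, "")[[1]]
  if (length(ra) != length(rb)) stop("alignment rows differ in length")
  both <- ra != "-" & rb != "-"
  if (!any(both)) stop("alignment has no dually aligned columns")
  identity <- sum(ra[both] == rb[both]) / sum(both)
  longer <- max(sum(ra != "-"), sum(rb != "-"))
  c(identity = identity, coverage = sum(both) / longer)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Threads each ungapped CDS through its gapped protein row so that every
#' amino-acid column maps to one codon column; protein gaps become `"---"`.
#' The translation of each codon must match the aligned residue.
#'
#' @param aln a `protein_alignment`.
#' @param cds_a,cds_b coding sequences (no terminal stop) of the ungapped rows.
#' @return an object of class `codon_alignment`: list with character vectors
#'   `codons_a`, `codons_b` (elements codons or `"---"`) and `n_codons`.
#' @export
backtranslate <- function(aln, cds_a, cds_b) {
  thread <- function(row, cds, side) {
    res <- strsplit(row, "")[[1]]
    n_res <- sum(res != "-")
    if (nchar(cds) != 3L * n_res) {
      stop(sprintf("CDS length %d does not match %d aligned residues (%s)",
                   nchar(cds), n_res, side))
    }
    codons <- substring(cds, seq(1, nchar(cds), by = 3), seq(3, nchar(cds), by = 3))
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    tr <- translate_codons(out)
    ok <- is.na(tr) | tr == res | res == "X"
    if (!all(ok)) {
      stop(sprintf("translation mismatch (%s) at codon column %d",
                   side, which(!ok)[1]))
    }
    out
  }
  structure(
    list(
      codons_a = thread(aln$row_a, toupper(cds_a), "a"),
      codons_b = thread(aln$row_b, toupper(cds_b), "b"),
      n_codons = nchar(aln$row_a)
    ),
    class = "codon_alignment"
  )
}

codon_alignment_from_cds <- function(cds_a, cds_b) {
  ## convenience for equal-length, gap-free codon sequences
  stopifnot(nchar(cds_a) == nchar(cds_b), nchar(cds_a) %% 3 == 0)
  idx <- seq(1, nchar(cds_a), by = 3)
  structure(
    list(
      codons_a = substring(toupper(cds_a), idx, idx + 2),
      codons_b = substring(toupper(cds_b), idx, idx + 2),
      n_codons = length(idx)
    ),
    class = "codon_alignment"
  )
}

#' Nei-Gojobori (1986) KA and KS from a codon alignment
#'
#' Counts synonymous (S) and nonsynonymous (N) sites as per-codon fractions of
#' the three possible single-nucleotide changes, averaged over the two
#' sequences; single-nucleotide changes producing a stop codon count as
#' nonsynonymous. Differences between aligned codons are averaged over all
#' minimal substitution paths, excluding paths through stop codons. The
#' Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` is applied separately to
#' the synonymous and nonsynonymous proportions.
#'
#' Codon columns with a gap, an internal stop codon, or a non-ACGT character
#' on either side are excluded from counting (with a warning for stops and
#' ambiguity codes, or an error when `on_bad_codon = "error"`).
#'
#' @param caln a `codon_alignment` from [backtranslate()].
#' @param on_bad_codon `"warn"` (skip the column) or `"error"`.
#' @return an object of class `divergence_estimate`: list with `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ka_ks` (NA when undefined),
#'   `n_codons_used` and `method = "NG86-JC"`.
#' @export
ng86_ka_ks <- function(caln, on_bad_codon = c("warn", "error")) {
  on_bad_codon <- match.arg(on_bad_codon)
  tabs <- codon_tables()
  a <- caln$codons_a
  b <- caln$codons_b

  usable <- a != "---" & b != "---"
  bad <- usable & (grepl("[^ACGT]", a) | grepl("[^ACGT]", b))
  if (any(bad)) {
    msg <- sprintf("%d codon column(s) with ambiguous nucleotides", sum(bad))
    if (on_bad_codon == "error") stop(msg) else warning(msg, call. = FALSE)
    usable <- usable & !bad
  }
  ia <- ib <- integer(0)
  if (any(usable)) {
    ia <- codon_index(a[usable])
    ib <- codon_index(b[usable])
    stops <- tabs$aa[ia] == "*" | tabs$aa[ib] == "*"
    if (any(stops)) {
      msg <- sprintf("%d codon column(s) containing internal stop codons", sum(stops))
      if (on_bad_codon == "error") stop(msg) else warning(msg, call. = FALSE)
      ia <- ia[!stops]
      ib <- ib[!stops]
    }
  }
  n_used <- length(ia)
  if (n_used == 0L) stop("no usable codon columns for NG86 estimation")

  S <- (sum(tabs$syn_sites[ia]) + sum(tabs$syn_sites[ib])) / 2
  N <- 3 * n_used - S
  Sd <- sum(tabs$sd_mat[cbind(ia, ib)])
  Nd <- sum(tabs$nd_mat[cbind(ia, ib)])
  pS <- Sd / S
  pN <- Nd / N

  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS)
  Ka <- jc(pN)
  ka_ks <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks

  structure(
    list(
      S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      Ks = Ks, Ka = Ka, ka_ks = ka_ks,
      n_codons_used = n_used, method = "NG86-JC"
    ),
    class = "divergence_estimate"
  )
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "NG86 divergence over %d codons: Ka = %.4f, Ks = %.4f, Ka/Ks = %s\n",
    x$n_codons_used, x$Ka, x$Ks,
    if (is.na(x$ka_ks)) "undefined" else sprintf("%.4f", x$ka_ks)
  ))
  invisible(x)
}

#' Estimate divergence for a table of gene pairs
#'
#' For each pair: align the representative proteins, compute identity and
#' coverage, back-translate to codons, and estimate KA/KS by NG86. Pairs with
#' `ka`, `ks` (and optionally `ka_ks`) override columns in `pairs` keep the
#' supplied estimates (method tag `"external"`), so externally computed values
#' can be injected.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` and optionally
#'   `label`, `ka`, `ks`, `ka_ks`.
#' @param records gene records from [read_gene_records()].
#' @return data.frame with one row per pair: `gene_a`, `gene_b`, `label`,
#'   `identity`, `coverage`, `ka`, `ks`, `ka_ks`, `method`, `error`.
#' @export
pair_divergence <- function(pairs, records) {
  rec_idx <- match(pairs$gene_a, records$gene_id)
  rec_idx_b <- match(pairs$gene_b, records$gene_id)
  n <- nrow(pairs)
  out <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    label = if ("label" %in% names(pairs)) pairs$label else rep("unknown", n),
    identity = NA_real_, coverage = NA_real_,
    ka = NA_real_, ks = NA_real_, ka_ks = NA_real_,
    method = NA_character_, error = NA_character_,
    stringsAsFactors = FALSE
  )
  has_override <- all(c("ka", "ks") %in% names(pairs))
  for (i in seq_len(n)) {
    if (has_override && !is.na(pairs$ka[i]) && !is.na(pairs$ks[i])) {
      out$ka[i] <- pairs$ka[i]
      out$ks[i] <- pairs$ks[i]
      out$ka_ks[i] <- if ("ka_ks" %in% names(pairs) && !is.na(pairs$ka_ks[i])) {
        pairs$ka_ks[i]
      } else if (pairs$ks[i] > 0) pairs$ka[i] / pairs$ks[i] else NA_real_
      out$method[i] <- "external"
      if (!is.na(rec_idx[i]) && !is.na(rec_idx_b[i])) {
        aln <- align_pair(records$protein[rec_idx[i]], records$protein[rec_idx_b[i]])
        out$identity[i] <- aln$identity
        out$coverage[i] <- aln$coverage
      } else {
        out$identity[i] <- 1
        out$coverage[i] <- 1
      }
      next
    }
    if (is.na(rec_idx[i]) || is.na(rec_idx_b[i])) {
      out$error[i] <- "missing_sequence"
      next
    }
    res <- tryCatch({
      aln <- align_pair(records$protein[rec_idx[i]], records$protein[rec_idx_b[i]])
      caln <- backtranslate(aln, records$cds[rec_idx[i]], records$cds[rec_idx_b[i]])
      est <- ng86_ka_ks(caln)
      list(aln = aln, est = est)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
      next
    }
    out$identity[i] <- res$aln$identity
    out$coverage[i] <- res$aln$coverage
    out$ka[i] <- res$est$Ka
    out$ks[i] <- res$est$Ks
    out$ka_ks[i] <- res$est$ka_ks
    out$method[i] <- res$est$method
  }
  out
}

#' Filter duplicate pairs on identity, coverage and KS
#'
#' Keeps a pair iff `identity >= min_identity`, `coverage >= min_coverage`
#' and `ks <= max_ks` (boundary values are kept; the strict inequalities
#' reject). Pairs with a recorded error are dropped with that reason.
#'
#' @param divergence output of [pair_divergence()].
#' @param min_identity,min_coverage,max_ks filter thresholds.
#' @return list with `kept` (rows passing all filters) and `rejected`
#'   (rows with a semicolon-separated `reason` column).
#' @export
filter_pairs <- function(divergence, min_identity = 0.30, min_coverage = 0.50,
                         max_ks = 3.0) {
  reason <- character(nrow(divergence))
  add <- function(reason, which, tag) {
    reason[which] <- ifelse(reason[which] == "", tag, paste(reason[which], tag, sep = ";"))
    reason
  }
  has_err <- !is.na(divergence$error)
  reason <- add(reason, has_err, ifelse(
    divergence$error[has_err] == "missing_sequence", "missing_sequence", "estimation_error"
  ))
  ok <- !has_err
  reason <- add(reason, ok & divergence$identity < min_identity, "identity")
  reason <- add(reason, ok & divergence$coverage < min_coverage, "coverage")
  reason <- add(reason, ok & (is.na(divergence$ks) | divergence$ks > max_ks), "ks")
  kept <- reason == ""
  rejected <- divergence[!kept, , drop = FALSE]
  rejected$reason <- reason[!kept]
  list(kept = divergence[kept, , drop = FALSE], rejected = rejected)
}
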