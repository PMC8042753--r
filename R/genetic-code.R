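## Codon bookkeeping shared by the NG86 estimator and the sequence simulator.
## Codons are indexed 1..64 as 16*b1 + 4*b2 + b3 + 1 with A=0, C=1, G=2, T=3.

BASES <- c("A", "C", "G", "T")

codon_index <- function(codons) {
  b <- matrix(match(unlist(strsplit(codons, "")), BASES) - 1L, nrow = 3)
  as.integer(16L * b[1, ] + 4L * b[2, ] + b[3, ] + 1L)
}

index_codon <- function(idx) {
  i <- idx - 1L
  paste0(BASES[i %/% 16L + 1L], BASES[(i %/% 4L) %% 4L + 1L], BASES[i %% 4L + 1L])
}

## Package-local cache for the code tables and NG86 lookup matrices.
.dd_cache <- new.env(parent = emptyenv())

#' @importFrom utils data
codon_tables <- function() {
  if (!is.null(.dd_cache$aa)) {
    return(.dd_cache)
  }
  all_codons <- index_codon(1:64)
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[all_codons])

  ## Neighbours: neighbours[[i]] is the 9 codons one nucleotide away from i.
  neighbours <- vector("list", 64)
  for (i in 1:64) {
    cod <- strsplit(all_codons[i], "")[[1]]
    nb <- integer(0)
    for (pos in 1:3) {
      for (alt in setdiff(BASES, cod[pos])) {
        mut <- cod
        mut[pos] <- alt
        nb <- c(nb, codon_index(paste(mut, collapse = "")))
      }
    }
    neighbours[[i]] <- nb
  }

  ## Synonymous site count per codon: at each position the fraction of the 3
  ## single-nucleotide changes that preserve the amino acid. Changes creating
  ## a stop codon count as nonsynonymous; stop codons themselves carry NA.
  syn_sites <- numeric(64)
  for (i in 1:64) {
    if (aa[i] == "*") {
      syn_sites[i] <- NA_real_
      next
    }
    syn_sites[i] <- sum(aa[neighbours[[i]]] == aa[i] & aa[neighbours[[i]]] != "*") / 3
  }

  ## Pairwise difference counts averaged over minimal substitution paths.
  sd_mat <- matrix(NA_real_, 64, 64)
  nd_mat <- matrix(NA_real_, 64, 64)
  for (i in 1:64) {
    if (aa[i] == "*") next
    for (j in i:64) {
      if (aa[j] == "*") next
      cnt <- path_average_counts(i, j, aa)
      sd_mat[i, j] <- sd_mat[j, i] <- cnt[1]
      nd_mat[i, j] <- nd_mat[j, i] <- cnt[2]
    }
  }

  .dd_cache$codons <- all_codons
  .dd_cache$aa <- aa
  .dd_cache$neighbours <- neighbours
  .dd_cache$syn_sites <- syn_sites
  .dd_cache$sd_mat <- sd_mat
  .dd_cache$nd_mat <- nd_mat
  .dd_cache$sense <- which(aa != "*")
  .dd_cache
}

## Average synonymous/nonsynonymous difference counts between two codons over
## all minimal substitution paths; paths passing through a stop codon are
## excluded (if every path does, all paths are used).
path_average_counts <- function(i, j, aa) {
  ci <- strsplit(index_codon(i), "")[[1]]
  cj <- strsplit(index_codon(j), "")[[1]]
  diff_pos <- which(ci != cj)
  k <- length(diff_pos)
  if (k == 0L) {
    return(c(0, 0))
  }
  perms <- permutations_of(diff_pos)
  tally <- function(skip_stops) {
    acc <- matrix(NA_real_, nrow = nrow(perms), ncol = 2)
    for (p in seq_len(nrow(perms))) {
      cur <- ci
      sd <- nd <- 0
      ok <- TRUE
      for (pos in perms[p, ]) {
        prev_aa <- aa[codon_index(paste(cur, collapse = ""))]
        cur[pos] <- cj[pos]
        cur_idx <- codon_index(paste(cur, collapse = ""))
        cur_aa <- aa[cur_idx]
        if (cur_aa == "*" && skip_stops) {
          ok <- FALSE
          break
        }
        if (cur_aa == prev_aa && cur_aa != "*") sd <- sd + 1 else nd <- nd + 1
      }
      if (ok) acc[p, ] <- c(sd, nd)
    }
    acc[stats::complete.cases(acc), , drop = FALSE]
  }
  valid <- tally(skip_stops = TRUE)
  if (nrow(valid) == 0L) valid <- tally(skip_stops = FALSE)
  colMeans(valid)
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) {
    return(matrix(x, 1, 1))
  }
  out <- NULL
  for (i in seq_len(n)) {
    sub <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], sub))
  }
  out
}

## Translate a vector of codon strings ("---" allowed) to amino acids.
translate_codons <- function(codons) {
  tabs <- codon_tables()
  out <- rep(NA_character_, length(codons))
  is_gap <- codons == "---"
  valid <- !is_gap & !grepl("[^ACGT]", codons)
  out[valid] <- tabs$aa[codon_index(codons[valid])]
  out[is_gap] <- "-"
  out
}
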