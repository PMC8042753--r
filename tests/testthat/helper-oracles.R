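# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. These deliberately re-derive everything
# from first principles (Biostrings::GENETIC_CODE, explicit enumeration)
# rather than calling package internals.

.gc <- Biostrings::GENETIC_CODE
.bases <- c("A", "C", "G", "T")

oracle_split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

oracle_syn_sites <- function(codon) {
  aa <- .gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(.bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (.gc[[mut]] == aa && .gc[[mut]] != "*") s <- s + 1 / 3
    }
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# average (syn, nonsyn) difference counts between two codons over minimal
# substitution paths, excluding paths through stop codons
oracle_codon_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  walk <- function(order, allow_stops) {
    cur <- ca
    sd <- nd <- 0
    for (p in order) {
      prev_aa <- .gc[[cur]]
      substr(cur, p, p) <- substr(cb, p, p)
      aa <- .gc[[cur]]
      if (aa == "*" && !allow_stops) return(NULL)
      if (aa == prev_aa && aa != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(oracle_perms(pos), walk, allow_stops = FALSE))
  if (length(res) == 0) {
    res <- lapply(oracle_perms(pos), walk, allow_stops = TRUE)
  }
  colMeans(do.call(rbind, res))
}

oracle_ng86 <- function(cds_a, cds_b) {
  ca <- oracle_split_codons(cds_a)
  cb <- oracle_split_codons(cds_b)
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(mapply(oracle_codon_diffs, ca, cb))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(d[1] / S)
  Ka <- jc(d[2] / N)
  list(S = S, N = N, Sd = d[1], Nd = d[2], Ks = Ks, Ka = Ka)
}

random_sense_cds <- function(n_codons) {
  sense <- names(.gc)[.gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Spearman rho from explicitly computed average ranks
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    })
  }
  rx <- rk(x)
  ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ROC AUC as the explicit pairwise-comparison U statistic
oracle_auc <- function(scores, labels, positive = "high") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

oracle_chi2_uncorrected <- function(tab) {
  tab <- tab * 1.0  # avoid integer overflow in (ad - bc)^2
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# hypergeometric upper-tail P(X >= k) by direct summation
oracle_hyper_ge <- function(k, n_term, n_bg, n_fg) {
  kk <- k:min(n_term, n_fg)
  sum(choose(n_term, kk) * choose(n_bg - n_term, n_fg - kk)) / choose(n_bg, n_fg)
}

# linearly interpolated percentile (type-7 definition, derived independently)
oracle_percentile <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}
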