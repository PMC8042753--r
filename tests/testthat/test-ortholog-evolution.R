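toy_triplets <- function(n_low = 10, n_high = 10, ret_low = 8, ret_high = 2) {
  data.frame(
    at_gene = sprintf("t%02d", 1:(n_low + n_high)),
    al_gene = c(
      ifelse(seq_len(n_low) <= ret_low, sprintf("al%02d", 1:n_low), NA),
      ifelse(seq_len(n_high) <= ret_high, sprintf("al%02d", n_low + 1:n_high), NA)
    ),
    br_gene = NA_character_,
    class = rep(c("low", "high"), c(n_low, n_high)),
    mechanism = "wgd",
    stringsAsFactors = FALSE
  )
}

test_that("retention rates and their chi-squared comparison match direct counts", {
  trip <- toy_triplets()
  res <- retention_analysis(trip)
  cls <- res[res$species == "al" & res$stratum == "class", ]
  expect_equal(cls$rate[cls$group == "low"], 0.8)
  expect_equal(cls$rate[cls$group == "high"], 0.2)
  expect_equal(
    cls$p[1],
    chi2_2x2(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))$p.value
  )

  all_there <- trip
  all_there$al_gene <- paste0("al", seq_len(nrow(trip)))
  res2 <- retention_analysis(all_there)
  expect_true(all(res2$rate[res2$species == "al"] == 1))

  # empty stratum (no tandem pairs) is omitted with a note
  expect_true(any(grepl("tandem", attr(res, "notes"))))
})

test_that("branch decomposition recovers hand-constructed synonymous distances", {
  # GGN codons: all third-position changes are synonymous (4-fold box).
  # at == al, br differs from both at 6 third positions: the Al branch gets
  # length 0 and the Br branch the whole at-br synonymous distance.
  at <- strrep("GGG", 12)
  al <- at
  br <- paste0(strrep("GGA", 6), strrep("GGG", 6))
  b <- branch_ka_ks(at, al, br)
  expect_equal(b$al$Ks, 0)
  expect_equal(b$al$Ka, 0)
  pair <- ng86_ka_ks(dupdiverge:::codon_alignment_from_cds(at, br))
  expect_equal(b$br$Ks, pair$Ks)
  expect_equal(b$br$Ka, 0)
  expect_equal(b$al$branch, "AS1->Al")
  expect_equal(b$br$branch, "AS2->Br")
})

test_that("equidistant tips split each pairwise distance evenly", {
  # three sequences pairwise-differing at disjoint synonymous positions:
  # every pairwise distance is equal and each branch gets half of it
  at <- paste0("GGA", strrep("GGG", 2), strrep("CCG", 9))
  al <- paste0("GGG", "GGA", "GGG", strrep("CCG", 9))
  br <- paste0(strrep("GGG", 2), "GGA", strrep("CCG", 9))
  d <- ng86_ka_ks(dupdiverge:::codon_alignment_from_cds(at, al))
  b <- branch_ka_ks(at, al, br)
  expect_equal(b$al$Ks, d$Ks / 2)
  expect_equal(b$br$Ks, d$Ks / 2)
})

test_that("branch estimates on evolved triplets recover planted branch lengths", {
  set.seed(61)
  tabs <- dupdiverge:::codon_tables()
  ks_al <- ks_br <- numeric(12)
  for (i in 1:12) {
    anc <- dupdiverge:::random_sense_codons(300, tabs)
    at <- paste(dupdiverge:::index_codon(
      dupdiverge:::evolve_codons(anc, 0.10, 0.2, tabs)), collapse = "")
    al <- paste(dupdiverge:::index_codon(
      dupdiverge:::evolve_codons(anc, 0.10, 0.2, tabs)), collapse = "")
    br <- paste(dupdiverge:::index_codon(
      dupdiverge:::evolve_codons(anc, 0.40, 0.2, tabs)), collapse = "")
    b <- branch_ka_ks(at, al, br)
    ks_al[i] <- b$al$Ks
    ks_br[i] <- b$br$Ks
    expect_true(b$al$Ka >= 0 && b$al$Ks >= 0 && b$br$Ka >= 0 && b$br$Ks >= 0)
  }
  expect_equal(median(ks_al), 0.10, tolerance = 0.35)
  expect_equal(median(ks_br), 0.40, tolerance = 0.25)
})

test_that("selection calls follow the Fisher procedure on allocated counts", {
  mk <- function(Nd, Sd, N = 600, S = 300) {
    structure(
      list(branch = "AS1->Al", Ka = Nd / N, Ks = Sd / S,
           ka_ks = (Nd / N) / (Sd / S), Sd = Sd, Nd = Nd, S = S, N = N,
           truncated = FALSE),
      class = "branch_estimate"
    )
  }
  expect_equal(selection_call(mk(0, 20))$call, "purifying")
  expect_equal(
    selection_call(mk(0, 20))$p.value,
    fisher.test(matrix(c(0, 20, 600, 300), 2, byrow = TRUE))$p.value
  )
  expect_equal(selection_call(mk(40, 2))$call, "positive")
  expect_equal(
    selection_call(mk(40, 2))$p.value,
    fisher.test(matrix(c(40, 2, 600, 300), 2, byrow = TRUE))$p.value
  )
  # differences proportional to sites: neutral
  expect_equal(selection_call(mk(20, 10))$call, "neutral")
  z <- selection_call(mk(0, 0))
  expect_equal(z$call, "neutral")
  expect_equal(z$flag, "no_differences")
  expect_equal(selection_call(NULL)$call, "undetermined")
})

test_that("selection proportions partition groups and flag planted omega contrasts", {
  set.seed(71)
  bt <- rbind(
    data.frame(at_gene = sprintf("h%02d", 1:20), class = "high",
               mechanism = "tandem", branch = "AS1->Al", ka = 0.3, ks = 0.15,
               ka_ks = 2, p = 0.01, call = "positive"),
    data.frame(at_gene = sprintf("l%02d", 1:20), class = "low",
               mechanism = "wgd", branch = "AS1->Al", ka = 0.02, ks = 0.15,
               ka_ks = 0.13, p = 0.001, call = "purifying")
  )
  props <- selection_proportions(bt)
  hi <- props[props$class == "high", ]
  lo <- props[props$class == "low", ]
  expect_equal(hi$prop_positive, 1.0)
  expect_equal(lo$prop_purifying, 1.0)
  expect_gt(hi$prop_positive, hi$overall_prop_positive)

  singles <- data.frame(branch = "AS1->Al", ka_ks = rnorm(50, 0.3, 0.05))
  props2 <- selection_proportions(bt, singletons = singles)
  expect_lt(props2$p_vs_singletons[props2$class == "low"], 0.01)
})

test_that("bootstrap support is deterministic and saturates for large effects", {
  trip <- toy_triplets(n_low = 40, n_high = 40, ret_low = 36, ret_high = 4)
  pred <- function(d) {
    r <- aggregate(!is.na(d$al_gene), list(class = d$class), mean)
    r$x[r$class == "low"] > r$x[r$class == "high"]
  }
  s1 <- bootstrap_support(trip, pred, n_boot = 50, seed = 5)
  s2 <- bootstrap_support(trip, pred, n_boot = 50, seed = 5)
  expect_identical(s1, s2)
  expect_equal(s1, 1.0)
})
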