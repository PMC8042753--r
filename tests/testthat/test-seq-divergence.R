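test_that("FASTA records are parsed, uppercased and stop-stripped", {
  cds <- tempfile(fileext = ".fa")
  pep <- tempfile(fileext = ".fa")
  writeLines(c(">g1 desc", "atggct", ">g2", "ATGGCTTAA"), cds)
  writeLines(c(">g1 desc", "MA", ">g2", "MA"), pep)
  rec <- read_gene_records(cds, pep)
  expect_equal(sort(rec$gene_id), c("g1", "g2"))
  expect_equal(rec$cds[rec$gene_id == "g1"], "ATGGCT")
  expect_equal(rec$cds[rec$gene_id == "g2"], "ATGGCT")  # terminal TAA removed

  writeLines(c(">g1", "ATGGCTA"), cds)  # length 7 for a 2-aa protein
  writeLines(c(">g1", "MA"), pep)
  expect_error(read_gene_records(cds, pep), "length mismatch.*g1")
})

test_that("identity and coverage follow the stated definitions", {
  a <- align_pair("MKV", "MKV")
  expect_equal(a$identity, 1.0)
  expect_equal(a$coverage, 1.0)

  imp <- align_pair("MK-V", "MKAV", aligned = TRUE)
  expect_equal(imp$identity, 1.0)        # 3 identical / 3 dually aligned
  expect_equal(imp$coverage, 0.75)       # 3 dually aligned / longer seq 4

  gapped <- align_pair("MKV", "MV")      # one internal gap
  expect_equal(gapped$row_b, "M-V")
  expect_equal(gapped$identity, 1.0)
  expect_equal(gapped$coverage, 2 / 3)

  expect_error(align_pair("", "MV"), "empty")
  expect_error(align_pair("M-", "V-", aligned = TRUE), "gap-in-both")
  expect_error(align_pair("M-", "-V", aligned = TRUE), "dually aligned")
})

test_that("back-translation threads codons through the protein alignment", {
  aln <- align_pair("MA", "MA")
  caln <- backtranslate(aln, "ATGGCT", "ATGGCA")
  expect_equal(caln$codons_a, c("ATG", "GCT"))
  expect_equal(caln$codons_b, c("ATG", "GCA"))

  aln2 <- align_pair("MKV", "MV")
  caln2 <- backtranslate(aln2, "ATGAAAGTT", "ATGGTT")
  expect_equal(sum(caln2$codons_b == "---"), 1L)

  expect_error(backtranslate(aln, "ATGGC", "ATGGCA"), "CDS length")
  expect_error(backtranslate(aln, "ATGTTT", "ATGGCA"), "translation mismatch")
})

test_that("NG86 reproduces hand-computed site and difference counts", {
  caln <- dupdiverge:::codon_alignment_from_cds("TTTGAAGGG", "TTCGAAGGG")
  est <- ng86_ka_ks(caln)
  expect_equal(est$S, 5 / 3)
  expect_equal(est$N, 22 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$pS, 0.6)
  expect_equal(est$Ks, -0.75 * log(0.2))
  expect_equal(est$Ka, 0)
  expect_equal(est$ka_ks, 0)  # Ks defined and positive, so the ratio is 0

  ident <- ng86_ka_ks(dupdiverge:::codon_alignment_from_cds(
    strrep("ATGGCTGAA", 4), strrep("ATGGCTGAA", 4)
  ))
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
  expect_true(is.na(ident$ka_ks))
})

test_that("NG86 multi-path differences match exhaustive enumeration", {
  # two-difference codon pair resolved by averaging the 2 minimal paths
  est <- ng86_ka_ks(dupdiverge:::codon_alignment_from_cds("TTT", "GTA"))
  orc <- oracle_ng86("TTT", "GTA")
  expect_equal(est$Sd, orc$Sd)
  expect_equal(est$Nd, orc$Nd)
  expect_equal(est$S, orc$S)

  set.seed(11)
  for (i in 1:40) {
    n <- sample(1:5, 1)
    a <- random_sense_cds(n)
    b <- random_sense_cds(n)
    est <- ng86_ka_ks(dupdiverge:::codon_alignment_from_cds(a, b))
    orc <- oracle_ng86(a, b)
    expect_equal(est$S, orc$S, tolerance = 1e-12)
    expect_equal(est$Sd, orc$Sd, tolerance = 1e-12)
    expect_equal(est$Nd, orc$Nd, tolerance = 1e-12)
    expect_equal(est$Ks, orc$Ks, tolerance = 1e-12)
    expect_equal(est$Ka, orc$Ka, tolerance = 1e-12)
  }
})

test_that("NG86 site counts conserve 3 sites per codon and are symmetric", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    a <- random_sense_cds(n)
    b <- random_sense_cds(n)
    ab <- ng86_ka_ks(dupdiverge:::codon_alignment_from_cds(a, b))
    ba <- ng86_ka_ks(dupdiverge:::codon_alignment_from_cds(b, a))
    expect_equal(ab$S + ab$N, 3 * ab$n_codons_used, tolerance = 1e-9)
    expect_equal(ab$Ks, ba$Ks)
    expect_equal(ab$Ka, ba$Ka)
  }
})

test_that("gap, stop and ambiguous codon columns are excluded from counting", {
  caln <- structure(
    list(
      codons_a = c("ATG", "---", "TAA", "ANG", "GGG"),
      codons_b = c("ATG", "GCT", "GCA", "AAG", "GGA"),
      n_codons = 5L
    ),
    class = "codon_alignment"
  )
  est <- suppressWarnings(ng86_ka_ks(caln))
  expect_equal(est$n_codons_used, 2L)  # only ATG/ATG and GGG/GGA columns
  w <- capture_warnings(ng86_ka_ks(caln))
  expect_match(w, "ambiguous", all = FALSE)
  expect_match(w, "stop", all = FALSE)
  expect_error(
    ng86_ka_ks(caln, on_bad_codon = "error"), "stop|ambiguous"
  )
  empty <- structure(
    list(codons_a = "---", codons_b = "GCT", n_codons = 1L),
    class = "codon_alignment"
  )
  expect_error(ng86_ka_ks(empty), "no usable codon columns")
})

test_that("pair filters keep boundary values and report rejection reasons", {
  div <- data.frame(
    gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
    label = "unknown",
    identity = c(0.29, 0.90, 0.30, 0.90, 0.90),
    coverage = c(0.90, 0.49, 0.50, 0.90, 0.90),
    ka = 0.1, ks = c(0.5, 0.5, 3.0, 3.5, 0.5),
    ka_ks = 0.2, method = "NG86-JC", error = NA_character_,
    stringsAsFactors = FALSE
  )
  res <- filter_pairs(div)
  expect_equal(res$kept$gene_a, c("a3", "a5"))  # boundaries 0.30/0.50/3.0 kept
  expect_equal(res$rejected$reason[res$rejected$gene_a == "a1"], "identity")
  expect_equal(res$rejected$reason[res$rejected$gene_a == "a2"], "coverage")
  expect_equal(res$rejected$reason[res$rejected$gene_a == "a4"], "ks")

  # idempotent and order-independent
  again <- filter_pairs(res$kept)
  expect_equal(again$kept, res$kept)
  shuffled <- filter_pairs(div[5:1, ])
  expect_equal(sort(shuffled$kept$gene_a), sort(res$kept$gene_a))

  div$error[2] <- "missing_sequence"
  res2 <- filter_pairs(div)
  expect_true("missing_sequence" %in% res2$rejected$reason)
})

test_that("externally supplied divergence estimates override computation", {
  pairs <- data.frame(
    gene_a = "x1", gene_b = "x2", label = "high",
    ka = 0.12, ks = 0.60, ka_ks = 0.2, stringsAsFactors = FALSE
  )
  records <- data.frame(
    gene_id = character(), cds = character(), protein = character(),
    stringsAsFactors = FALSE
  )
  out <- pair_divergence(pairs, records)
  expect_equal(out$ka, 0.12)
  expect_equal(out$ks, 0.60)
  expect_equal(out$method, "external")
})
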