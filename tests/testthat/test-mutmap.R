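test_that("HGVS parsing handles one- and three-letter missense and delins", {
  r <- parse_hgvs_p("p.R4810K")
  expect_equal(r$type, "missense")
  expect_equal(r$ref_aa, "R"); expect_equal(r$position, 4810L)
  expect_equal(r$alt_aa, "K")
  r3 <- parse_hgvs_p("p.Arg4753Lys")
  expect_equal(unlist(r3[, c("ref_aa", "alt_aa")], use.names = FALSE), c("R", "K"))
  expect_equal(r3$position, 4753L)
  d <- parse_hgvs_p("p.3941_3999delinsGSGSG")
  expect_equal(d$type, "delins")
  expect_error(parse_hgvs_p("p.R4810"), class = "structkit_bad-hgvs")
  expect_error(parse_hgvs_p("R4810K"), class = "structkit_bad-hgvs")
  expect_error(parse_hgvs_p("p.R4810R"), class = "structkit_bad-hgvs")  # ref == alt
})

test_that("parse -> format -> parse is the identity on missense strings", {
  set.seed(61)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  ref <- sample(aas, 50, replace = TRUE)
  alt <- vapply(ref, function(a) sample(setdiff(aas, a), 1), character(1))
  s <- paste0("p.", ref, sample(1:5000, 50), alt)
  expect_identical(format_hgvs_p(parse_hgvs_p(s)), s)
})

test_that("reference validation distinguishes ok, mismatch and out-of-range", {
  seqv <- paste0(strrep("A", 9), "R", strrep("A", 5))   # R at position 10
  rec <- parse_hgvs_p(c("p.R10K", "p.Q10K", "p.A9999V"))
  expect_equal(validate_reference(rec, seqv), c("ok", "mismatch", "out_of_range"))
})

test_that("global alignment reproduces the toy gap case and identical inputs", {
  al <- pairwise_align("ACDEFG", "ACEFG")
  expect_equal(al$aligned_a, "ACDEFG")
  expect_equal(al$aligned_b, "AC-EFG")            # one gap opposite D
  M <- structkit:::blosum62()
  s <- random_sequence(20)
  ident <- pairwise_align(s, s)
  expect_equal(ident$aligned_a, s)                # gapless
  expect_equal(ident$score, sum(diag(M)[match(strsplit(s, "")[[1]],
                                              rownames(M))]))
})

test_that("alignment scores match an exhaustive dynamic-programming oracle", {
  M <- structkit:::blosum62()
  set.seed(62)
  for (k in 1:15) {
    a <- random_sequence(12); b <- random_sequence(sample(8:14, 1))
    expect_equal(pairwise_align(a, b)$score, bf_global_score(a, b, M))
  }
})

test_that("numbering transfer follows gaps, is monotone and round-trips", {
  al <- as_alignment("ACDEFG", "AC-EFG")
  expect_equal(transfer_numbering(4, al), 3L)     # E maps over the gap
  expect_true(is.na(transfer_numbering(3, al)))   # D aligned to gap
  expect_error(transfer_numbering(9, al), class = "structkit_out-of-range")
  ident <- as_alignment("ACDEF", "ACDEF")
  expect_equal(transfer_numbering(1:5, ident), 1:5)

  set.seed(63)
  for (k in 1:20) {
    a <- random_sequence(sample(15:30, 1))
    b <- random_sequence(sample(15:30, 1))
    al <- pairwise_align(a, b)
    fwd <- transfer_numbering(seq_len(nchar(a)), al, from = "a")
    ok <- !is.na(fwd)
    expect_true(all(diff(fwd[ok]) > 0))           # strictly monotone
    back <- transfer_numbering(fwd[ok], al, from = "b")
    expect_equal(back, seq_len(nchar(a))[ok])     # round trip
  }
})

test_that("CADD severity bins partition scores left-closed", {
  expect_equal(bin_severity(c(10, 17, 25)), c("low", "mid", "high"))
  expect_equal(bin_severity(c(0, 15, 20)), c("low", "mid", "high"))
  expect_error(bin_severity(-1), class = "structkit_bad-cadd")
  set.seed(64)
  x <- runif(500, 0, 45)
  b <- bin_severity(x)
  expect_true(all(b %in% c("low", "mid", "high")))  # exactly one bin each
  expect_equal(b == "low", x < 15)
  expect_equal(b == "high", x >= 20)
})

test_that("severe-mutation clustering counts are exact on planted tables", {
  tab <- rnf213_domains()
  mt <- make_mutation_table(50, 28, 21, tab, seed = 7)
  cc <- domain_cluster_counts(mt$records, tab)
  expect_equal(cc$n_severe, 28)
  expect_equal(cc$n_in_target, 21)
  expect_equal(cc$n_unmapped, 0)
  # empty input
  cc0 <- domain_cluster_counts(mt$records[0, ], tab)
  expect_equal(c(cc0$n_severe, cc0$n_in_target), c(0L, 0L))
  # a threshold of exactly 20 is not severe (strict >)
  rec <- mt$records[1:2, ]
  rec$cadd <- c(20, 20.0001)
  expect_equal(domain_cluster_counts(rec, tab)$n_severe, 1)
  # records without mapped positions are set aside, not counted in target
  rec2 <- mt$records
  rec2$mapped_position[1:5] <- NA
  cc2 <- domain_cluster_counts(rec2, tab)
  expect_equal(cc2$n_severe, 28)
  expect_equal(cc2$n_unmapped, sum(rec2$cadd[1:5] > 20))
})

test_that("clustering counts equal a brute-force scan on random tables", {
  tab <- rnf213_domains()
  tgt <- structkit:::domain_residues(tab, e3_subdomains(), "subdomain")
  set.seed(65)
  for (k in 1:50) {
    n_tot <- sample(5:40, 1)
    n_sev <- sample(0:n_tot, 1)
    n_in <- sample(0:n_sev, 1)
    mt <- make_mutation_table(n_tot, n_sev, n_in, tab, seed = 1000 + k)
    cc <- domain_cluster_counts(mt$records, tab)
    r <- mt$records
    bf_sev <- sum(r$cadd > 20)
    bf_in <- sum(r$cadd > 20 & r$mapped_position %in% tgt)
    expect_equal(cc$n_severe, bf_sev)
    expect_equal(cc$n_in_target, bf_in)
    expect_equal(c(bf_sev, bf_in), c(n_sev, n_in))  # generator bookkeeping
  }
})

test_that("enrichment reports a small hypergeometric tail for clustered placement", {
  tab <- domain_table(c("hot", "cold"), c(1, 101), c(100, 1000))
  # all severe mutations inside a domain covering 10% of residues
  mt <- make_mutation_table(6, 6, 6, tab, target_domains = "hot",
                            level = "module", seed = 9)
  en <- domain_enrichment(mt$records, tab, target_domains = "hot",
                          level = "module")
  expect_lt(en$p_value, 0.01)
  expect_gt(en$odds_ratio, 1)
  # exact tail against direct phyper bookkeeping
  expect_equal(en$p_value, phyper(5, 100, 900, 6, lower.tail = FALSE))
  # degenerate: no severe mutations
  mt0 <- make_mutation_table(5, 0, 0, tab, target_domains = "hot",
                             level = "module", seed = 10)
  expect_true(domain_enrichment(mt0$records, tab, target_domains = "hot",
                                level = "module")$degenerate)
})

test_that("uniform placement gives odds ratios centered near 1", {
  tab <- domain_table(c("t", "rest"), c(1, 501), c(500, 1000))
  set.seed(66)
  ors <- replicate(200, {
    pos <- sample(1000, 30)
    k <- sum(pos <= 500)
    (k / max(30 - k, 0.5)) / (500 / 500)
  })
  expect_equal(median(ors), 1, tolerance = 0.25)
})

test_that("mutation tables round-trip through TSV with severity bins", {
  mt <- make_mutation_table(20, 10, 5, seed = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(hgvs_p = mt$records$hgvs_p, cadd = mt$records$cadd,
                         genomic = "chr17:whatever"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- load_mutation_table(f)
  expect_equal(nrow(rec), 20)
  expect_equal(rec$cadd, mt$records$cadd)
  expect_equal(rec$severity_bin, bin_severity(rec$cadd))
  # a 57-residue N-terminal insert shifts numbering as human 4810 -> mouse 4753
  al <- as_alignment(paste0(strrep("A", 57), strrep("G", 4763)),
                     paste0(strrep("-", 57), strrep("G", 4763)))
  expect_equal(transfer_numbering(4810, al), 4753L)
})
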