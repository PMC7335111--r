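test_that("variant application and translation follow the codon table", {
  fx <- generate_variant_fixture(1)
  tms <- setNames(fx$transcripts, vapply(fx$transcripts, `[[`, "", "id"))

  # zero variants: reference translation, exactly
  ref <- translate_with_variants(tms$t1, fx$variants[0, ])[[1]]
  expect_equal(ref$protein, "MAGSLVTEKALDGSIVRAGSTLNEK")

  # missense SNV substitutes a single residue (L5 -> P)
  v1 <- fx$variants[fx$variants$transcript == "t1", ]
  r1 <- translate_with_variants(tms$t1, v1)[[1]]
  expect_equal(r1$protein, "MAGSPVTEKALDGSIVRAGSTLNEK")
  expect_equal(c(r1$var_start, r1$var_end), c(5, 5))

  # frame-preserving deletion removes one residue (D10)
  v2 <- fx$variants[fx$variants$transcript == "t2", ]
  r2 <- translate_with_variants(tms$t2, v2)[[1]]
  expect_equal(r2$protein, "MSTVAGELKDLGSVAAARTLSGEK")

  # stop gain emits nothing
  v3 <- fx$variants[fx$variants$transcript == "t3", ]
  r3 <- translate_with_variants(tms$t3, v3)[[1]]
  expect_true(r3$skipped)
  expect_null(r3$protein)

  # stop loss: exactly five extra residues where depth > 3, then stop
  v4 <- fx$variants[fx$variants$transcript == "t4", ]
  r4 <- translate_with_variants(tms$t4, v4)[[1]]
  expect_true(r4$stop_loss)
  expect_equal(nchar(r4$protein), nchar("MKAGSTLVDEAAR") + 5)
  expect_equal(r4$protein, "MKAGSTLVDEAARQAGSV")

  # a new in-frame stop inside the extension terminates it earlier
  seq_stop <- paste0(substr(tms$t4$seq, 1, 45), "TGA",
                     substr(tms$t4$seq, 49, nchar(tms$t4$seq)))
  tm_stop <- transcript_model("t4b", seq_stop, fpkm = 30, depth = tms$t4$depth)
  r5 <- translate_with_variants(tm_stop, v4)[[1]]
  expect_equal(nchar(r5$protein), nchar("MKAGSTLVDEAAR") + 2)

  expect_error(translate_with_variants(tms$t1,
                                       data.frame(pos = 9999, ref = "A",
                                                  alt = "C")),
               "out of range")
})

test_that("tryptic digestion matches the exhaustive cleavage-subset oracle", {
  cases <- list(
    list(prot = "MAGSPVTEKALDGSIVRAGSTLNEK", vs = 5, ve = 5),
    list(prot = "MKAGSTLVDEAARQAGSV", vs = 14, ve = 18),
    list(prot = "AAAKBBBRCCCKDDDD", vs = 10, ve = 10),
    list(prot = "KRKRKRKRAAAAAAAA", vs = 9, ve = 9),
    list(prot = "AAAKPBBBRCCC", vs = 6, ve = 6)          # KP: no cleavage
  )
  for (cs in cases) {
    ours <- digest(cs$prot, var_start = cs$vs, var_end = cs$ve)
    oracle <- brute_digest(cs$prot, cs$vs, cs$ve)
    expect_setequal(unique(ours$peptide), oracle)
  }
  # K followed by P is not a cleavage site
  d <- digest("AAAKPBBBRCCCDDD", var_start = 1, var_end = 15, min_len = 1)
  expect_true("AAAKPBBBR" %in% d$peptide)
  # 7-residue candidates are dropped at the default minimum length
  d7 <- digest("AAAKBBBK", var_start = 6, var_end = 6)
  expect_false(any(nchar(d7$peptide) < 8))
  # stop-loss products get the extended N-terminal allowance
  many_k <- "AKBKCKDKEKFKGHIJLMNV"
  strict <- digest(many_k, var_start = 13, var_end = 20, max_missed = 3)
  loose <- digest(many_k, var_start = 13, var_end = 20, max_missed = 3,
                  stop_loss = TRUE)
  expect_gt(nrow(loose), nrow(strict))
  expect_setequal(unique(loose$peptide),
                  brute_digest(many_k, 13, 20, n_allow = 5))
})

test_that("variant FASTA construction applies expression and stop-gain rules with deterministic output", {
  fx <- generate_variant_fixture(1)
  db <- build_variant_fasta(fx$transcripts, fx$variants)
  expect_gt(nrow(db), 0)
  expect_false(any(db$transcript == "t3"))      # stop gain -> no record
  expect_false(any(db$transcript == "t_low"))   # FPKM <= 1 -> excluded
  expect_true(any(grepl("P", db$peptide[db$transcript == "t1"])))
  expect_true(all(nchar(db$peptide) >= 8))
  db2 <- build_variant_fasta(fx$transcripts, fx$variants)
  expect_identical(db, db2)
  expect_false(anyDuplicated(db$peptide) > 0)

  # only stop-gain variants -> empty database
  only_sg <- fx$variants[fx$variants$transcript == "t3", ]
  expect_equal(nrow(build_variant_fasta(fx$transcripts, only_sg)), 0)

  # FASTA round trip through Biostrings
  out <- tempfile(fileext = ".fasta")
  build_variant_fasta(fx$transcripts, fx$variants, out = out)
  back <- Biostrings::readAAStringSet(out)
  expect_equal(as.character(unname(back)), db$peptide)
})

test_that("Jaccard coefficient and mutation distances satisfy their metric properties", {
  expect_equal(jaccard(letters[1:4], letters[1:4]), 1)
  expect_equal(jaccard(letters[1:4], letters[5:8]), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_true(is.na(jaccard(character(0), character(0))))

  sets <- list(s1 = c("TP53", "EGFR", "PTEN"),
               s2 = c("TP53", "EGFR"),
               s3 = c("RB1", "PTEN"),
               s4 = c("NF1"))
  d <- mutation_distance_matrix(sets)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
  expect_warning(mutation_distance_matrix(list(a = character(0),
                                               b = character(0))),
                 "convention")
})
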