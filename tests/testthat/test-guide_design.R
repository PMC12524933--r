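test_that("design_params enforces the nested-length invariant", {
  p <- design_params()
  expect_equal(p$spacer_len, 20L)
  expect_equal(p$seed_len, 12L)
  expect_equal(p$exact_core_len, 7L)
  expect_equal(p$min_pairing_run, 12L)
  expect_equal(p$pam, "NGG")
  expect_error(design_params(seed_len = 25), class = "crispri_input_error")
  expect_error(design_params(pam = "NGGG"), class = "crispri_input_error")
})

test_that("a feature without CC on its sense strand yields no candidate", {
  withr::local_seed(201)
  sense <- sense_with_site(120, 30)
  sense_no_cc <- gsub("CC", "CA", sense)  # destroy the planted site too
  emb <- embed_feature(sense_no_cc)
  expect_equal(nrow(enumerate_candidates(emb$feature, emb$genome)), 0L)
})

test_that("a single planted site is recovered with the documented geometry", {
  withr::local_seed(202)
  for (strand in c("+", "-")) {
    sense <- sense_with_site(60, 9)
    emb <- embed_feature(sense, strand = strand)
    cand <- enumerate_candidates(emb$feature, emb$genome)
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$dist5, 9L)
    expect_identical(cand$spacer, oracle_revcomp(substr(sense, 13, 32)))
    expect_identical(cand$pam, oracle_revcomp(substr(sense, 10, 12)))
    expect_identical(cand$seed, substr(cand$spacer, 9, 20))
    # self-consistency: re-extract the genomic slice on pam_strand
    rec_seq <- emb$genome[[1]]$seq
    slice <- substr(rec_seq, cand$proto_start + 1, cand$proto_end)
    expect_identical(if (cand$pam_strand == "-") oracle_revcomp(slice) else slice,
                     cand$spacer)
    pam_slice <- if (cand$pam_strand == "-")
      oracle_revcomp(substr(rec_seq, cand$proto_start - 2, cand$proto_start))
    else substr(rec_seq, cand$proto_end + 1, cand$proto_end + 3)
    expect_identical(pam_slice, cand$pam)
  }
})

test_that("every emitted candidate has a 20-nt spacer and an NGG PAM", {
  withr::local_seed(203)
  fx <- generate_fixture(demo_fixture_spec(203))
  for (i in seq_len(nrow(fx$features))) {
    cand <- suppressMessages(
      enumerate_candidates(fx$features[i, ], fx$genome))
    if (!nrow(cand)) next
    expect_true(all(nchar(cand$spacer) == 20L))
    expect_true(all(grepl("^[ACGT]GG$", cand$pam)))
    expect_true(all(cand$dist5 >= 0 &
                      cand$dist5 <= (fx$features$end[i] - fx$features$start[i]) - 20L))
  }
})

test_that("enumeration agrees with a naive position loop on random features", {
  withr::local_seed(204)
  for (rep in 1:25) {
    len <- sample(30:400, 1)
    strand <- sample(c("+", "-"), 1)
    emb <- embed_feature(random_dna(len), strand = strand, ftype = "other")
    sense <- feature_seq(emb$feature, emb$genome)
    cand <- suppressMessages(enumerate_candidates(emb$feature, emb$genome))
    cand <- cand[order(cand$dist5), ]
    exp_off <- oracle_enumerate_offsets(sense)
    # candidates with N never occur here (no N generated)
    expect_equal(cand$dist5, exp_off)
    for (j in seq_len(nrow(cand)))
      expect_identical(cand$spacer[j],
                       oracle_revcomp(substr(sense, cand$dist5[j] + 4,
                                             cand$dist5[j] + 23)))
  }
})

test_that("the specificity pattern is seed + NGG with 14 informative bases", {
  p <- design_params()
  pat <- specificity_pattern(strrep("AC", 6), p)
  expect_equal(as.character(pat), "ACACACACACACNGG")
  expect_equal(attr(pat, "informative_length"), 14L)
  # informative length is seed_len + 2 for any seed
  withr::local_seed(205)
  for (i in 1:20) {
    s <- random_dna(12)
    expect_equal(attr(specificity_pattern(s, p), "informative_length"), 14L)
  }
})

test_that("binding-site counting matches the oracle on planted duplicates", {
  withr::local_seed(206)
  sense <- sense_with_site(80, 12)
  emb <- embed_feature(sense, flank = 400)
  cand <- enumerate_candidates(emb$feature, emb$genome)
  expect_equal(nrow(cand), 1L)
  # the candidate's own site counts once
  expect_equal(count_binding_sites(cand, emb$genome)$count, 1L)

  # plant two extra copies of seed+PAM, one on the reverse strand
  instance <- paste0(cand$seed, "A", "GG")
  seq <- emb$genome[[1]]$seq
  substr(seq, 11, 25) <- instance
  substr(seq, 41, 55) <- oracle_revcomp(instance)
  genome2 <- make_genome(c(rec1 = seq))
  res <- count_binding_sites(cand, genome2)
  expect_equal(res$count, 3L)
  expect_equal(res$count, oracle_count_sites(genome2, cand$seed))
  expect_setequal(res$hits$strand, c("+", "-"))
  # hit text obeys the pattern invariant
  expect_true(all(substr(res$hits$matched_text, 1, 12) == cand$seed))
  expect_true(all(substr(res$hits$matched_text, 14, 15) == "GG"))
})

test_that("a seed followed by a non-GG tail does not count", {
  withr::local_seed(207)
  sense <- sense_with_site(80, 12)
  emb <- embed_feature(sense, flank = 400)
  cand <- enumerate_candidates(emb$feature, emb$genome)
  seq <- emb$genome[[1]]$seq
  substr(seq, 11, 25) <- paste0(cand$seed, "ACG")   # no GG at PAM 2-3
  genome2 <- make_genome(c(rec1 = seq))
  expect_equal(count_binding_sites(cand, genome2)$count, 1L)
})

test_that("N in the genome never matches any pattern position", {
  cand_seed <- strrep("A", 12)
  genome <- make_genome(c(
    rec1 = paste0("TTTT", strrep("A", 12), "TGG", "TTTT",
                  strrep("A", 11), "N", "TGG", "TTTT")))
  res <- count_binding_sites(cand_seed, genome)
  expect_equal(res$count, 1L)
  # N at the wildcard PAM position does not match either
  genome2 <- make_genome(c(rec1 = paste0("TTTT", strrep("A", 12), "NGG", "TTTT")))
  expect_equal(count_binding_sites(cand_seed, genome2)$count, 0L)
})

test_that("circular records are scanned across the origin, linear ones not", {
  seed <- strrep("A", 12)
  # site split across the origin: ...AAAAAA | AAAAAATGG...
  seq <- paste0(strrep("A", 6), "TGG", random_dna(60, 0.5), strrep("A", 6))
  lin <- make_genome(c(rec1 = seq), circular = FALSE)
  cir <- make_genome(c(rec1 = seq), circular = TRUE)
  expect_equal(count_binding_sites(seed, lin)$count,
               oracle_count_sites(lin, seed))
  expect_equal(count_binding_sites(seed, cir)$count,
               oracle_count_sites(cir, seed))
  expect_gt(count_binding_sites(seed, cir)$count,
            count_binding_sites(seed, lin)$count)
})

test_that("filter_unique partitions candidates and keeps the unique ones", {
  fx <- generate_fixture(demo_fixture_spec(208))
  f <- fx$features[fx$features$id == "opA1", ]
  cand <- enumerate_candidates(f, fx$genome)
  res <- filter_unique(cand, fx$genome, design_params())
  expect_equal(nrow(res$kept) + nrow(res$discarded), nrow(cand))
  expect_equal(nrow(merge(res$kept, res$discarded, by = "dist5")), 0L)
  expect_true(all(res$kept$offtarget_count == 1L))
  # the fixture plants 2 extra copies of the dist5=120 candidate
  expect_equal(res$discarded$dist5, 120L)
  expect_equal(res$discarded$offtarget_count, 3L)
  # with require_unique = FALSE nothing is discarded
  p2 <- design_params(require_unique = FALSE)
  res2 <- filter_unique(cand, fx$genome, p2)
  expect_equal(nrow(res2$discarded), 0L)
  expect_equal(sort(res2$kept$offtarget_count), c(1L, 3L))
})

test_that("pairing validation counts the PAM-proximal run", {
  withr::local_seed(209)
  spacer <- random_dna(20)
  expect_true(validate_pairing(spacer, spacer)$pass)
  expect_equal(validate_pairing(spacer, spacer)$run, 20L)
  # exhaustive single-mismatch sweep: positions 1-12 fail, 13-20 pass
  for (p in 1:20) {
    site <- spacer
    idx <- 21 - p                      # position p from the PAM (3' end)
    old <- substr(site, idx, idx)
    substr(site, idx, idx) <- setdiff(c("A", "C", "G", "T"), old)[1]
    v <- validate_pairing(spacer, site)
    expect_equal(v$run, p - 1L)
    expect_equal(v$mismatch_positions, p)
    expect_equal(v$pass, p >= 13L, label = sprintf("position %d", p))
  }
  expect_error(validate_pairing(spacer, "ACGT"), class = "crispri_input_error")
})

test_that("ranking is by 5'-proximity with deterministic tie-breaks", {
  withr::local_seed(210)
  sense <- sense_with_site(120, 40)
  b <- strsplit(sense, "")[[1]]
  b[6] <- "C"; b[7] <- "C"; b[8] <- "A"   # second site at offset 5
  if (b[5] == "C") b[5] <- "A"
  emb <- embed_feature(paste(b, collapse = ""))
  cand <- enumerate_candidates(emb$feature, emb$genome)
  ranked <- rank_candidates(cand)
  expect_equal(ranked$dist5, sort(ranked$dist5))
  expect_equal(ranked$dist5[1], 5L)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
})

test_that("a 4/12 GC seed reports ~33% and is flagged low-GC", {
  # construct, via the full enumeration pipeline, a candidate whose seed
  # has exactly 4 G/C among its 12 bases
  withr::local_seed(211)
  repeat {
    proto <- random_dna(20, 0.3)
    seed <- oracle_revcomp(substr(proto, 1, 12))
    if (!grepl("CC", proto) &&
        sum(strsplit(seed, "")[[1]] %in% c("G", "C")) == 4) break
  }
  sense <- sense_with_site(60, 9, proto_sense = proto)
  emb <- embed_feature(sense)
  cand <- rank_candidates(enumerate_candidates(emb$feature, emb$genome))
  expect_equal(nrow(cand), 1L)
  expect_equal(sum(strsplit(cand$seed, "")[[1]] %in% c("G", "C")), 4)
  expect_equal(cand$seed_gc, 4 / 12, tolerance = 1e-12)
  expect_true(cand$low_gc_flag)
})

test_that("an effective-range seed (42-58% GC) is not flagged", {
  withr::local_seed(213)
  repeat {
    proto <- random_dna(20, 0.5)
    seed <- oracle_revcomp(substr(proto, 1, 12))
    ngc <- sum(strsplit(seed, "")[[1]] %in% c("G", "C"))
    if (!grepl("CC", proto) && ngc >= 5 && ngc <= 7) break
  }
  sense <- sense_with_site(60, 9, proto_sense = proto)
  emb <- embed_feature(sense)
  cand <- rank_candidates(enumerate_candidates(emb$feature, emb$genome))
  expect_equal(nrow(cand), 1L)
  expect_false(cand$low_gc_flag)
})

test_that("guide TSV and BED outputs carry the ranked table", {
  fx <- generate_fixture(demo_fixture_spec(212))
  res <- design_guides(fx$features, fx$genome)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_guide_tsv(res$guides, tsv)
  write_guide_bed(res$guides, bed)
  back <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(nrow(back), nrow(res$guides))
  bed_tab <- utils::read.delim(bed, header = FALSE)
  expect_equal(ncol(bed_tab), 6L)
  expect_true(all(bed_tab$V2 >= 0 & bed_tab$V3 > bed_tab$V2))
})
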