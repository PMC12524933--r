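# A candidate planted at codon-aligned offset o covers: PAM codon at o/3
# (a proline, CCN), then the seed spans the next 4 codons of the CDS.

planted_cds_case <- function(n_codons = 30, o = 12, seed_codons = NULL,
                             strand = "+") {
  cds <- toy_cds_with_site(n_codons, o, seed_codons)
  emb <- embed_feature(cds, strand = strand)
  cand <- enumerate_candidates(emb$feature, emb$genome)
  cand <- cand[cand$dist5 == o, ]          # seed codons may add a second site
  stopifnot(nrow(cand) == 1)
  list(feature = emb$feature, genome = emb$genome, cds = cds, cand = cand)
}

test_that("guide-to-codon mapping annotates the footprint arithmetically", {
  withr::local_seed(301)
  cs <- planted_cds_case(30, 12)
  m <- map_guide_to_codons(cs$feature, cs$cand)
  # footprint = PAM [12,15) + protospacer [15,35): codons 4..11
  expect_equal(m$codon_index, 4:11)
  expect_equal(sum(m$overlap_nt), 23L)
  # protospacer starts exactly at a codon boundary: full 3-nt overlaps
  # until the trailing codon, which holds only the protospacer's last 2 nt
  expect_true(all(m$overlap_nt[m$codon_index %in% 4:10] == 3L))
  expect_equal(m$overlap_nt[m$codon_index == 11], 2L)
  expect_true(m$in_pam[m$codon_index == 4])
  # seed = sense [15, 27): codons 5..8
  expect_equal(m$codon_index[m$in_seed], 5:8)
  # 7-nt core = sense [15, 22): codons 5..7
  expect_equal(m$codon_index[m$in_core7], 5:7)
  expect_false(any(m$immutable))
  expect_error(map_guide_to_codons(
    make_feature("x", "rec1", 0, 30, ftype = "sRNA"), cs$cand),
    class = "crispri_input_error")
})

test_that("a start codon overlapping the footprint is flagged immutable", {
  withr::local_seed(302)
  cds <- toy_cds_with_site(30, 3)          # PAM codon right after ATG
  emb <- embed_feature(cds)
  cand <- enumerate_candidates(emb$feature, emb$genome)
  cand <- cand[cand$dist5 == 3, ]
  m <- map_guide_to_codons(emb$feature, cand)
  expect_false(0L %in% m$codon_index)      # footprint starts at codon 1
  # shift: a candidate at offset 0 would cover codon 0; emulate by checking
  # the immutable flag on the stop codon instead
  cds2 <- toy_cds_with_site(10, 6)         # 30-nt CDS, footprint to the end
  emb2 <- embed_feature(cds2)
  cand2 <- enumerate_candidates(emb2$feature, emb2$genome)
  cand2 <- cand2[cand2$dist5 == 6, ]
  m2 <- map_guide_to_codons(emb2$feature, cand2)
  expect_true(m2$immutable[m2$codon_index == 9])
})

test_that("a proline codon in the seed admits a single-codon escape", {
  withr::local_seed(303)
  cs <- planted_cds_case(30, 12, seed_codons = c("CCA", "GAA", "AAA", "TTT"))
  al <- design_escape_alleles(cs$feature, cs$cand, cs$cds,
                              min_codon_changes = 1)
  singles <- al[al$n_changed_codons == 1 & grepl(":CC", al$changed_codons) &
                  al$nt_changes_in_seed >= 1, ]
  expect_gt(nrow(singles), 0L)
  # proline family: CCT/CCC/CCA/CCG all encode P
  expect_identical(translate_cds(singles$mutant_cds[1]),
                   translate_cds(cs$cds))
})

test_that("a seed of Met/Trp codons admits no escape and warns", {
  withr::local_seed(304)
  cs <- planted_cds_case(30, 12, seed_codons = c("ATG", "TGG", "ATG", "TGG"))
  # eligible codons: the seed codons (no synonyms) and the PAM proline,
  # whose synonymous changes cannot break CC nor touch the seed
  expect_warning(
    al <- design_escape_alleles(cs$feature, cs$cand, cs$cds,
                                min_codon_changes = 1),
    "no escape allele|no synonymous")
  expect_equal(nrow(al), 0L)
})

test_that("escape enumeration matches a brute-force single/double oracle", {
  withr::local_seed(305)
  cs <- planted_cds_case(30, 12)
  al <- design_escape_alleles(cs$feature, cs$cand, cs$cds,
                              min_codon_changes = 1)
  # oracle: nested loops over all synonymous single and double codon
  # substitutions at codons overlapping seed or PAM (codons 4..8 here),
  # filtered by the same acceptance rule
  tb <- codon_table_11()
  codons <- substring(cs$cds, seq(1, nchar(cs$cds), 3), seq(3, nchar(cs$cds), 3))
  eligible <- 4:8                          # PAM codon + 4 seed codons
  seed_win <- c(15L, 27L); gg_pos <- c(12L, 13L)   # 0-based sense
  syn <- function(cd) setdiff(names(tb$code)[tb$code == tb$code[[cd]]], cd)
  oracle <- character(0)
  apply_subs <- function(subs) {
    cd2 <- codons
    for (s in subs) cd2[s$j + 1] <- s$new
    paste(cd2, collapse = "")
  }
  accept <- function(mut, n_codons_changed) {
    d <- which(strsplit(mut, "")[[1]] != strsplit(cs$cds, "")[[1]]) - 1L
    in_seed <- sum(d >= seed_win[1] & d < seed_win[2])
    pam_dis <- any(d %in% gg_pos)
    (n_codons_changed >= 1) && (in_seed >= 1 || pam_dis)
  }
  for (j1 in eligible) for (n1 in syn(codons[j1 + 1])) {
    mut <- apply_subs(list(list(j = j1, new = n1)))
    if (accept(mut, 1)) oracle <- c(oracle, mut)
    for (j2 in eligible) if (j2 > j1) for (n2 in syn(codons[j2 + 1])) {
      mut2 <- apply_subs(list(list(j = j1, new = n1), list(j = j2, new = n2)))
      if (accept(mut2, 2)) oracle <- c(oracle, mut2)
    }
  }
  expect_setequal(al$mutant_cds, unique(oracle))
})

test_that("all emitted alleles are protein-identical and verified escapes", {
  withr::local_seed(306)
  for (strand in c("+", "-")) {
    cs <- planted_cds_case(40, 15, strand = strand)
    for (minc in 1:2) {
      al <- design_escape_alleles(cs$feature, cs$cand, cs$cds,
                                  min_codon_changes = minc)
      expect_gt(nrow(al), 0L)
      for (k in seq_len(nrow(al))) {
        expect_identical(translate_cds(al$mutant_cds[k]),
                         translate_cds(cs$cds))
        rep <- verify_escape(cs$cand, al$mutant_cds[k], cs$cds)
        expect_true(rep$escaped)
        expect_true(rep$protein_identical)
      }
      # default ordering puts core-7 changes first
      expect_equal(al$nt_changes_in_core7, sort(al$nt_changes_in_core7,
                                                decreasing = TRUE))
    }
  }
})

test_that("escape design is strand-symmetric", {
  withr::local_seed(307)
  cds <- toy_cds_with_site(30, 12)
  embp <- embed_feature(cds, strand = "+")
  embm <- embed_feature(cds, strand = "-")
  cp <- enumerate_candidates(embp$feature, embp$genome)
  cm <- enumerate_candidates(embm$feature, embm$genome)
  expect_identical(cp$spacer, cm$spacer)
  ap <- design_escape_alleles(embp$feature, cp, cds, min_codon_changes = 2)
  am <- design_escape_alleles(embm$feature, cm, cds, min_codon_changes = 2)
  expect_identical(ap$mutant_cds, am$mutant_cds)
})

test_that("verify_escape rejects non-escaping and malformed mutants", {
  withr::local_seed(308)
  cs <- planted_cds_case(30, 12)
  # change only codons outside the footprint: not an escape
  codons <- substring(cs$cds, seq(1, nchar(cs$cds), 3), seq(3, nchar(cs$cds), 3))
  out_j <- 20L
  alt <- setdiff(names(codon_table_11()$code)[
    codon_table_11()$code == codon_table_11()$code[[codons[out_j + 1]]]],
    codons[out_j + 1])[1]
  codons[out_j + 1] <- alt
  mut <- paste(codons, collapse = "")
  rep <- verify_escape(cs$cand, mut, cs$cds)
  expect_false(rep$escaped)
  expect_true(rep$pairing_pass)
  expect_equal(rep$nt_changes$outside, length(which(
    strsplit(mut, "")[[1]] != strsplit(cs$cds, "")[[1]])))
  # two seed changes suffice
  al <- design_escape_alleles(cs$feature, cs$cand, cs$cds, 2)
  two_seed <- al[al$nt_changes_in_seed >= 2 & !al$pam_disrupted, ][1, ]
  rep2 <- verify_escape(cs$cand, two_seed$mutant_cds, cs$cds)
  expect_true(rep2$escaped)
  expect_lt(rep2$run, 12L)
  # indels unsupported
  expect_error(verify_escape(cs$cand, paste0(cs$cds, "AAA"), cs$cds),
               class = "crispri_input_error")
})

test_that("escape variant listing is exact", {
  a <- "ATGAAACCA"
  b <- "ATGAAGCCG"
  v <- escape_variants(a, b)
  expect_equal(v$pos, c(6L, 9L))
  expect_equal(v$ref, c("A", "A"))
  expect_equal(v$alt, c("G", "G"))
})
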