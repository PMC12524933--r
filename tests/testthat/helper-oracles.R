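# Independent oracles and fixture builders. These deliberately avoid the
# package's own scanning/matching code paths: plain loops, substring
# comparisons, and third-party references (seqinr) only.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(COMP[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_translate <- function(x) {
  paste(seqinr::translate(seqinr::s2c(tolower(x)), numcode = 11),
        collapse = "")
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

make_genome <- function(seqs, circular = FALSE) {
  mapply(genome_record, names(seqs), seqs,
         MoreArgs = list(circular = circular),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

make_feature <- function(id, record_id, start, end, strand = "+",
                         ftype = "CDS", operon_id = id, operon_index = 0L) {
  data.frame(id = id, record_id = record_id, start = start, end = end,
             strand = strand, ftype = ftype, operon_id = operon_id,
             operon_index = operon_index, non_triplet = FALSE,
             stringsAsFactors = FALSE)
}

# naive enumeration of non-template-rule candidates from a feature's sense
# sequence: explicit position loop, independent of find_motif()
oracle_enumerate_offsets <- function(sense, spacer_len = 20L) {
  out <- integer(0)
  lim <- nchar(sense) - (spacer_len + 3L)
  i <- 0L
  while (i <= lim) {
    if (substr(sense, i + 1L, i + 1L) == "C" &&
        substr(sense, i + 2L, i + 2L) == "C")
      out <- c(out, i)
    i <- i + 1L
  }
  out
}

# naive genome-wide binding-site count for a seed + NGG pattern: vectorized
# substring comparison over every window on both strands, N never matches
oracle_count_sites <- function(genome, seed, seed_len = 12L) {
  count_one_strand <- function(s, L_keep) {
    n <- nchar(s)
    if (n < seed_len + 3L) return(0L)
    starts <- seq_len(n - seed_len - 2L)
    starts <- starts[starts <= L_keep]
    win <- substring(s, starts, starts + seed_len + 2L)
    ok <- substr(win, 1L, seed_len) == seed &
      substr(win, seed_len + 2L, seed_len + 3L) == "GG" &
      !grepl("N", win)
    sum(ok)
  }
  total <- 0L
  for (rec in genome) {
    L <- nchar(rec$seq)
    s <- if (rec$circular) paste0(rec$seq, substr(rec$seq, 1L, seed_len + 2L))
         else rec$seq
    total <- total + count_one_strand(s, L)
    # minus strand: scan the reverse complement; a window starting within
    # the original L positions of the rc corresponds to a distinct site
    total <- total + count_one_strand(oracle_revcomp(s),
                                      if (rec$circular) L else nchar(s))
  }
  total
}

# build a sense sequence free of CC, then splice a candidate site at offset
# o (CC + non-C base + a given 20-nt protospacer-region sequence)
sense_with_site <- function(len, o, proto_sense = NULL, gc = 0.4) {
  repeat {
    s <- random_dna(len, gc)
    if (!grepl("CC", s)) break
  }
  b <- strsplit(s, "")[[1]]
  b[o + 1] <- "C"; b[o + 2] <- "C"; b[o + 3] <- sample(c("A", "G", "T"), 1)
  if (o >= 1 && b[o] == "C") b[o] <- "A"
  if (!is.null(proto_sense)) {
    stopifnot(nchar(proto_sense) == 20L)
    b[(o + 4):(o + 23)] <- strsplit(proto_sense, "")[[1]]
    if (o + 24 <= len && b[o + 23] == "C" && b[o + 24] == "C")
      b[o + 24] <- "A"
  }
  paste(b, collapse = "")
}

# a toy CDS (triplet, ATG...TAA, no internal stop) carrying a candidate
# site at codon-aligned offset o, with chosen codons in the seed region
toy_cds_with_site <- function(n_codons, o, seed_codons = NULL) {
  stopifnot(o %% 3 == 0, o >= 3)
  pool <- c("GCT", "GAA", "AAA", "TTT", "GGT", "ATT", "CAT", "GTT")
  cods <- c("ATG", sample(pool, n_codons - 2, replace = TRUE), "TAA")
  cods[o / 3 + 1] <- "CCA"                      # the planted PAM codon
  if (!is.null(seed_codons))
    cods[(o / 3 + 2):(o / 3 + 1 + length(seed_codons))] <- seed_codons
  paste(cods, collapse = "")
}

# wrap a sense sequence into a one-record genome with flanks, returning
# the genome and the feature row (optionally on the minus strand)
embed_feature <- function(sense, id = "gene1", strand = "+",
                          ftype = "CDS", flank = 50L, gc = 0.4) {
  gseq <- if (strand == "-") oracle_revcomp(sense) else sense
  seqs <- c(rec1 = paste0(random_dna(flank, gc), gseq, random_dna(flank, gc)))
  genome <- make_genome(seqs)
  feature <- make_feature(id, "rec1", flank, flank + nchar(sense),
                          strand = strand, ftype = ftype)
  list(genome = genome, feature = feature)
}
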