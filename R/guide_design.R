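#' Guide design parameters
#'
#' Defaults encode the design rules for CRISPRi with S. pyogenes dCas9 in
#' bacteria: 20-nt spacers, an NGG PAM, a 12-nt PAM-proximal seed used for
#' the genome-wide uniqueness screen, a minimum contiguous pairing run of
#' 12 nt from the PAM, full complementarity over the 7 PAM-proximal
#' nucleotides, and a warning (not a filter) for seeds below 40% GC, since
#' low-GC seeds silence measurably but more weakly.
#'
#' @param spacer_len Spacer length in nt.
#' @param seed_len Seed (PAM-proximal) length in nt used for the uniqueness
#'   pattern.
#' @param exact_core_len Length of the PAM-proximal core that must pair
#'   perfectly.
#' @param min_pairing_run Minimum contiguous run of paired bases, counted
#'   from the PAM-proximal end, for a site to be considered bound.
#' @param pam PAM motif, 3 letters, `N` is a wildcard.
#' @param gc_warn_below Seed GC fraction below which a guide is flagged.
#' @param require_unique Discard guides with more than one genomic binding
#'   site.
#' @param strand_rule Which strand the sgRNA pairs with: `"non_template"`
#'   (the default; protospacer and PAM on the template strand, effective for
#'   CRISPRi elongation blocks within ORFs), `"template"`, or `"both"`.
#' @return An object of class `design_params`.
#' @export
design_params <- function(spacer_len = 20L, seed_len = 12L,
                          exact_core_len = 7L, min_pairing_run = 12L,
                          pam = "NGG", gc_warn_below = 0.40,
                          require_unique = TRUE,
                          strand_rule = c("non_template", "template", "both")) {
  strand_rule <- match.arg(strand_rule)
  spacer_len <- as.integer(spacer_len); seed_len <- as.integer(seed_len)
  exact_core_len <- as.integer(exact_core_len)
  min_pairing_run <- as.integer(min_pairing_run)
  pam <- toupper(pam)
  if (nchar(pam) != 3L || grepl("[^ACGTN]", pam))
    abort_input("pam must be 3 letters over {A,C,G,T,N}")
  if (!(exact_core_len <= min_pairing_run && min_pairing_run <= seed_len &&
        seed_len <= spacer_len))
    abort_input("need exact_core_len <= min_pairing_run <= seed_len <= spacer_len")
  if (gc_warn_below < 0 || gc_warn_below > 1)
    abort_input("gc_warn_below must be a fraction in [0,1]")
  structure(list(spacer_len = spacer_len, seed_len = seed_len,
                 exact_core_len = exact_core_len,
                 min_pairing_run = min_pairing_run, pam = pam,
                 gc_warn_below = gc_warn_below,
                 require_unique = isTRUE(require_unique),
                 strand_rule = strand_rule),
            class = "design_params")
}

# positions i (0-based) where motif (N = wildcard) occurs in seq
find_motif <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(integer(0))
  b <- chars(seq)
  ok <- rep(TRUE, n - m + 1L)
  mo <- chars(motif)
  for (k in seq_len(m)) {
    if (mo[k] == "N") next
    ok <- ok & b[seq_len(n - m + 1L) + (k - 1L)] == mo[k]
  }
  which(ok) - 1L
}

#' Enumerate candidate guides within a feature
#'
#' Under the default `non_template` rule the sgRNA must base-pair with the
#' non-template (sense) strand of the gene, which places the protospacer
#' and its PAM on the template strand. Operationally the feature's sense
#' sequence is scanned for the reverse-complemented PAM (`CCN` for NGG) at
#' sense offset `i`; the spacer is the reverse complement of the
#' `spacer_len` nt that follow, and `dist5 = i` measures how far the site
#' sits from the 5' (start-codon) end of the feature. Both protospacer and
#' PAM must lie entirely inside the feature. Candidates containing `N` are
#' dropped. `offtarget_count` and `rank` are -1 / NA until screening and
#' ranking.
#'
#' @param feature One-row feature data.frame (see [read_gff3()]).
#' @param genome List of [genome_record()] objects.
#' @param params [design_params()].
#' @return A candidate data.frame, one row per site (possibly zero rows).
#' @export
enumerate_candidates <- function(feature, genome, params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  feature <- as.data.frame(feature)[1L, ]
  sense <- feature_seq(feature, genome)
  flen <- nchar(sense)
  need <- params$spacer_len + 3L
  if (flen < need) {
    message(sprintf("feature %s (%d nt) shorter than spacer+PAM (%d nt): no candidates",
                    feature$id, flen, need))
    return(empty_candidate_df())
  }
  rows <- list()
  if (params$strand_rule %in% c("non_template", "both")) {
    cc <- find_motif(sense, revcomp(params$pam))
    cc <- cc[cc + 3L + params$spacer_len <= flen]
    for (i in cc) {
      rows[[length(rows) + 1L]] <-
        candidate_row(feature, sense, i, params, on_template = FALSE)
    }
  }
  if (params$strand_rule %in% c("template", "both")) {
    gg <- find_motif(sense, params$pam)
    gg <- gg[gg >= params$spacer_len & gg + 3L <= flen]
    for (p in gg) {
      rows[[length(rows) + 1L]] <-
        candidate_row(feature, sense, p, params, on_template = TRUE)
    }
  }
  if (!length(rows)) return(empty_candidate_df())
  out <- do.call(rbind, rows)
  out <- out[!grepl("N", paste0(out$spacer, out$pam)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# build one candidate at sense offset i; geometry differs by scan strand
candidate_row <- function(feature, sense, i, params, on_template) {
  sp <- params$spacer_len
  if (!on_template) {
    # sense[i, i+3) is the rev-comp PAM; protospacer is the next sp nt,
    # read on the strand opposite the feature
    spacer <- revcomp(sub0(sense, i + 3L, i + 3L + sp))
    pam <- revcomp(sub0(sense, i, i + 3L))
    dist5 <- i
    if (feature$strand == "+") {
      proto_start <- feature$start + i + 3L
      pam_strand <- "-"
    } else {
      proto_start <- feature$end - (i + 3L + sp)
      pam_strand <- "+"
    }
  } else {
    # PAM on the sense strand at [p, p+3); protospacer immediately 5' of it
    p <- i
    spacer <- sub0(sense, p - sp, p)
    pam <- sub0(sense, p, p + 3L)
    dist5 <- p - sp
    if (feature$strand == "+") {
      proto_start <- feature$start + p - sp
      pam_strand <- "+"
    } else {
      proto_start <- feature$end - p
      pam_strand <- "-"
    }
  }
  seed <- substr(spacer, sp - params$seed_len + 1L, sp)
  data.frame(
    feature_id = feature$id, record_id = feature$record_id,
    spacer = spacer, pam = pam,
    proto_start = proto_start, proto_end = proto_start + sp,
    pam_strand = pam_strand, dist5 = dist5,
    seed = seed, seed_gc = gc_frac(seed),
    offtarget_count = -1L, low_gc_flag = NA,
    rank = NA_integer_, on_template = on_template,
    stringsAsFactors = FALSE)
}

#' Genome-wide uniqueness search pattern for a guide
#'
#' The specificity region is the `seed_len`-nt seed plus the PAM with its
#' `N` position left as a wildcard: with the defaults, 12 informative seed
#' bases + GG = a 14-nt informative pattern.
#'
#' @param candidate One-row candidate data.frame, or a bare seed string.
#' @param params [design_params()].
#' @return The pattern string (e.g. `"ACACACACACACNGG"`), with attribute
#'   `informative_length` (number of non-wildcard positions).
#' @export
specificity_pattern <- function(candidate, params = design_params()) {
  seed <- if (is.character(candidate)) candidate else candidate$seed
  if (nchar(seed) != params$seed_len)
    abort_input(sprintf("seed must be %d nt", params$seed_len))
  assert_dna(seed, "seed", allow_n = FALSE)
  pat <- paste0(seed, params$pam)
  structure(pat, informative_length = nchar(gsub("N", "", pat)))
}

#' Count genomic binding sites of a guide
#'
#' Exhaustive exact matching of the specificity pattern (seed + PAM, `N`
#' wildcard) over both strands of every record; the origin is wrapped only
#' for circular records. `N` in the genome never satisfies any pattern
#' position, wildcard included. A candidate taken from the genome always
#' counts its own site, so unique means exactly 1.
#'
#' @param candidate One-row candidate data.frame (or bare seed string).
#' @param genome List of [genome_record()] objects.
#' @param params [design_params()].
#' @return A list with `count` and `hits` (data.frame: `record_id`,
#'   `start`, `end`, `strand`, `matched_text`; coordinates 0-based
#'   half-open on the plus strand, `end` may exceed the record length for a
#'   hit wrapping a circular origin).
#' @export
count_binding_sites <- function(candidate, genome, params = design_params()) {
  pat <- specificity_pattern(candidate, params)
  m <- nchar(pat)
  fwd <- Biostrings::DNAString(pat)
  rev <- Biostrings::reverseComplement(fwd)
  hits <- list()
  for (rec in genome) {
    L <- nchar(rec$seq)
    subj_seq <- if (rec$circular && L >= m)
      paste0(rec$seq, substr(rec$seq, 1L, m - 1L)) else rec$seq
    subj <- Biostrings::DNAString(subj_seq)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") fwd else rev
      mt <- Biostrings::matchPattern(q, subj, fixed = "subject")
      st <- BiocGenerics::start(mt) - 1L
      st <- st[st < L]            # wrapped duplicates start beyond the origin
      if (!length(st)) next
      txt_plus <- substr(rep(subj_seq, length(st)), st + 1L, st + m)
      keep <- !grepl("N", txt_plus)
      st <- st[keep]; txt_plus <- txt_plus[keep]
      if (!length(st)) next
      hits[[length(hits) + 1L]] <- data.frame(
        record_id = rec$id, start = st, end = st + m, strand = strand,
        matched_text = if (strand == "+") txt_plus else revcomp(txt_plus),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(record_id = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               matched_text = character(0), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  list(count = nrow(hits), hits = hits)
}

#' Screen candidates for genome-wide uniqueness
#'
#' Fills `offtarget_count` for every candidate and, when
#' `params$require_unique` is `TRUE`, splits candidates with more than one
#' genomic binding site into the discarded set (the self site counts, so
#' unique = exactly 1). With `require_unique = FALSE` everything is kept,
#' counts annotated.
#'
#' @param candidates Candidate data.frame from [enumerate_candidates()].
#' @param genome List of [genome_record()] objects.
#' @param params [design_params()].
#' @return A list with data.frames `kept` and `discarded` (a partition of
#'   the input).
#' @export
filter_unique <- function(candidates, genome, params = design_params()) {
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, discarded = candidates))
  candidates$offtarget_count <- vapply(seq_len(nrow(candidates)), function(i) {
    count_binding_sites(candidates[i, ], genome, params)$count
  }, 0L)
  if (params$require_unique) {
    keep <- candidates$offtarget_count == 1L
  } else {
    keep <- rep(TRUE, nrow(candidates))
  }
  list(kept = candidates[keep, , drop = FALSE],
       discarded = candidates[!keep, , drop = FALSE])
}

#' Assess spacer/site pairing by PAM-proximal run length
#'
#' A site is bound when the contiguous run of matched bases counted from
#' the PAM-proximal end reaches `min_pairing_run` (12 by default, which
#' subsumes the 7-nt perfect-core requirement). Positions are numbered from
#' the PAM: 1 = PAM-proximal.
#'
#' @param spacer Spacer, 5' to 3'.
#' @param site_seq Genomic protospacer instance on the PAM-bearing strand,
#'   same length and orientation (PAM presence is checked separately).
#' @param params [design_params()].
#' @return List with `pass`, `run` (matched run length from the PAM) and
#'   `mismatch_positions` (1 = PAM-proximal).
#' @export
validate_pairing <- function(spacer, site_seq, params = design_params()) {
  if (nchar(spacer) != nchar(site_seq))
    abort_input("spacer and site must have equal length")
  a <- rev(chars(spacer)); b <- rev(chars(site_seq))   # index 1 = PAM-proximal
  match_v <- a == b
  run <- if (!match_v[1L]) 0L else {
    mis <- which(!match_v)
    if (!length(mis)) length(match_v) else mis[1L] - 1L
  }
  list(pass = run >= params$min_pairing_run,
       run = as.integer(run),
       mismatch_positions = which(!match_v))
}

#' Rank screened candidates by 5'-proximity
#'
#' CRISPRi blocks transcript elongation, so guides closest to the 5' end
#' of the coding sequence silence the full gene: candidates are ordered by
#' ascending `dist5`, with deterministic tie-breaks (record, coordinate,
#' spacer). Seeds below `gc_warn_below` GC are flagged but not removed.
#'
#' @param candidates Candidate data.frame.
#' @param params [design_params()].
#' @return The data.frame reordered, with `rank` (1-based) and
#'   `low_gc_flag` filled in.
#' @export
rank_candidates <- function(candidates, params = design_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  o <- order(candidates$dist5, candidates$record_id,
             candidates$proto_start, candidates$spacer)
  out <- candidates[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$low_gc_flag <- out$seed_gc < params$gc_warn_below
  rownames(out) <- NULL
  out
}

#' Design ranked guides for a set of target features
#'
#' Convenience pipeline: enumerate, uniqueness-screen, and rank per
#' feature.
#'
#' @param features Feature data.frame.
#' @param genome List of [genome_record()] objects.
#' @param params [design_params()].
#' @param targets `"all"` or a character vector of feature ids.
#' @return List with `guides` (ranked, all targets), `discarded`
#'   (multi-site candidates with their counts), and `log` (character).
#' @export
design_guides <- function(features, genome, params = design_params(),
                          targets = "all") {
  if (!identical(targets, "all")) {
    missing <- setdiff(targets, features$id)
    if (length(missing))
      abort_input(sprintf("unknown target feature(s): %s",
                          paste(missing, collapse = ", ")))
    features <- features[features$id %in% targets, , drop = FALSE]
  }
  guides <- list(); discarded <- list(); log <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    cand <- enumerate_candidates(f, genome, params)
    if (nrow(cand) == 0L) {
      log <- c(log, sprintf("%s: no candidates (no PAM site or too short)", f$id))
      next
    }
    scr <- filter_unique(cand, genome, params)
    if (nrow(scr$discarded))
      log <- c(log, sprintf("%s: discarded %d multi-site candidate(s)",
                            f$id, nrow(scr$discarded)))
    ranked <- rank_candidates(scr$kept, params)
    if (nrow(ranked) && any(ranked$low_gc_flag))
      log <- c(log, sprintf("%s: %d candidate(s) flagged for seed GC < %.0f%%",
                            f$id, sum(ranked$low_gc_flag),
                            100 * params$gc_warn_below))
    guides[[length(guides) + 1L]] <- ranked
    discarded[[length(discarded) + 1L]] <- scr$discarded
  }
  list(guides = if (length(guides)) do.call(rbind, guides) else empty_candidate_df(),
       discarded = if (length(discarded)) do.call(rbind, discarded) else empty_candidate_df(),
       log = log)
}

#' Write a guide table as TSV
#'
#' @param guides Candidate data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_guide_tsv <- function(guides, path) {
  cols <- c("feature_id", "spacer", "pam", "record_id", "proto_start",
            "proto_end", "pam_strand", "dist5", "seed", "seed_gc",
            "offtarget_count", "low_gc_flag", "rank")
  write_commented_tsv(
    guides[, cols, drop = FALSE], path,
    c("crisprikit guide table",
      "coordinates: 0-based half-open, protospacer on pam_strand",
      "dist5: nt from the feature 5' end to the protospacer 5'-most base (feature orientation)",
      "seed_gc: fraction; offtarget_count includes the self site"))
}

#' Write guide coordinates as BED6
#'
#' BED is 0-based half-open; name is `feature_id|rank`, score the binding
#' site count (capped at 1000), strand the PAM-bearing strand.
#'
#' @param guides Candidate data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_guide_bed <- function(guides, path) {
  if (nrow(guides) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = guides$record_id,
    start = guides$proto_start,
    end = guides$proto_end,
    name = paste0(guides$feature_id, "|", guides$rank),
    score = pmin(pmax(guides$offtarget_count, 0L), 1000L),
    strand = guides$pam_strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
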