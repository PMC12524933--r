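# Deterministic synthetic genome/annotation generator. Feature sense
# sequences are generated free of the CC dinucleotide (the reverse
# complement of the NGG PAM), then candidate sites are planted explicitly,
# so the truth table (candidates per feature, off-target counts, census) is
# exact by construction and re-verified by an internal scan before the
# fixture is emitted. Designed around the default NGG design parameters.

#' Specify a synthetic fixture genome
#'
#' @param seed Integer RNG seed; generation is byte-reproducible.
#' @param record_length Length of each replicon (nt).
#' @param n_records Number of replicons; features live on the first,
#'   additional records are background (handy for planting off-target
#'   copies elsewhere).
#' @param gc Background GC fraction. Default 0.36, a low-GC firmicute-like
#'   composition.
#' @param genes Data.frame (`id`, `length`, `strand`, `operon_id`,
#'   `operon_index`) of CDS features; lengths must be triplet. `NULL` for
#'   none. Generated CDSs start ATG, end TAA, no internal stops.
#' @param planted_pams Data.frame (`feature_id`, `offset`): candidate sites
#'   planted at the given sense offsets. Offsets in CDS features must be
#'   codon-aligned (a proline codon is written there) and avoid the start
#'   and stop codons.
#' @param offtarget_copies Data.frame (`feature_id`, `offset`, `copies`):
#'   extra genomic copies of a planted candidate's seed+PAM instance,
#'   alternating strands, placed in intergenic background.
#' @param srnas Data.frame (`id`, `length`, `strand`, `targetable`): small
#'   RNA features; each targetable sRNA gets one planted candidate site at
#'   a random valid offset, non-targetable ones are kept free of sites
#'   (impossible geometrically when `length < spacer_len + 3`).
#' @param circular Logical: mark records circular.
#' @param max_retries Bounded regeneration attempts before declaring the
#'   spec infeasible.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, record_length = 6000L, n_records = 1L,
                         gc = 0.36, genes = NULL, planted_pams = NULL,
                         offtarget_copies = NULL, srnas = NULL,
                         circular = FALSE, max_retries = 1000L) {
  if (!is.numeric(seed) || length(seed) != 1L)
    abort_input("seed must be a single integer")
  if (gc <= 0 || gc >= 1) abort_input("gc must be in (0,1)")
  if (!is.null(genes)) {
    if (any(genes$length %% 3L != 0L))
      abort_input("gene lengths must be multiples of 3")
    if (anyDuplicated(genes$id)) abort_input("duplicate gene ids")
  }
  if (!is.null(planted_pams) && !is.null(genes)) {
    for (i in seq_len(nrow(planted_pams))) {
      fid <- planted_pams$feature_id[i]; o <- planted_pams$offset[i]
      g <- genes[genes$id == fid, ]
      if (nrow(g) == 1L) {
        if (o %% 3L != 0L)
          abort_input(sprintf("planted offset %d in CDS %s must be codon-aligned", o, fid))
        if (o < 3L || o + 23L > g$length - 3L)
          abort_input(sprintf("planted offset %d in CDS %s out of usable range", o, fid))
      }
    }
    off <- planted_pams[order(planted_pams$feature_id, planted_pams$offset), ]
    d <- diff(off$offset)
    same <- off$feature_id[-1L] == off$feature_id[-nrow(off)]
    if (any(same & d < 3L))
      abort_input("planted offsets within one feature must be >= 3 nt apart")
  }
  total_feat <- sum(genes$length %||% 0L) + sum(srnas$length %||% 0L)
  n_feat <- nrow(genes %||% data.frame()) + nrow(srnas %||% data.frame())
  if (record_length < total_feat + 40L * (n_feat + 1L))
    abort_input("record_length too small for the requested features")
  structure(list(seed = as.integer(seed), record_length = as.integer(record_length),
                 n_records = as.integer(n_records), gc = gc, genes = genes,
                 planted_pams = planted_pams, offtarget_copies = offtarget_copies,
                 srnas = srnas, circular = isTRUE(circular),
                 max_retries = as.integer(max_retries)),
            class = "fixture_spec")
}

random_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# break every CC dinucleotide (single left-to-right pass; replacements are
# never C, so no new CC appears)
clean_cc <- function(b) {
  n <- length(b)
  if (n < 2L) return(b)
  for (k in seq_len(n - 1L)) {
    if (b[k] == "C" && b[k + 1L] == "C")
      b[k + 1L] <- sample(c("A", "G", "T"), 1L)
  }
  b
}

# plant a candidate site (CC + non-C third base) at sense offset o in a
# CC-free character vector; guards against creating neighbouring CC pairs
plant_cc_site <- function(b, o) {
  b[o + 1L] <- "C"; b[o + 2L] <- "C"
  b[o + 3L] <- sample(c("A", "G", "T"), 1L)
  if (o >= 1L && b[o] == "C") b[o] <- sample(c("A", "G", "T"), 1L)
  b
}

# codons without CC inside and not stops; used for background CDS
cds_codon_pool <- function(table) {
  cods <- names(table$code)[table$code != "*"]
  cods[!grepl("CC", cods)]
}

gen_cds_sense <- function(len, planted, gc, table) {
  n_cod <- len %/% 3L
  pool <- cds_codon_pool(table)
  # GC-weighted codon sampling keeps composition near the target
  w <- (vapply(pool, function(cd) sum(chars(cd) %in% c("G", "C")), 0) / 3) * gc +
    (1 - vapply(pool, function(cd) sum(chars(cd) %in% c("G", "C")), 0) / 3) * (1 - gc)
  cods <- c("ATG", sample(pool, n_cod - 2L, replace = TRUE, prob = w), "TAA")
  for (o in planted) {
    j <- o %/% 3L
    cods[j + 1L] <- sample(c("CCA", "CCG", "CCT"), 1L)   # proline, third base non-C
    prev <- cods[j]
    if (substr(prev, 3L, 3L) == "C")
      cods[j] <- sample(pool[!endsWith(pool, "C")], 1L)
  }
  # break cross-codon CC outside planted sites
  b <- chars(paste0(cods, collapse = ""))
  keep <- unlist(lapply(planted, function(o) o + 1L))    # 1-based first C
  for (k in seq_len(length(b) - 1L)) {
    if (b[k] == "C" && b[k + 1L] == "C" && !(k %in% keep)) {
      # resample the whole codon containing position k+1 synonymously-free:
      # replace with a pool codon compatible at both junctions
      j <- (k) %/% 3L                                    # 0-based codon of k+1... approximate
      j <- ((k + 1L) - 1L) %/% 3L
      if (j %in% c(0L, n_cod - 1L) || (3L * j) %in% planted) next
      repl <- sample(pool[!startsWith(pool, "C") & !endsWith(pool, "C")], 1L)
      b[(3L * j + 1L):(3L * j + 3L)] <- chars(repl)
    }
  }
  paste0(b, collapse = "")
}

gen_srna_sense <- function(len, planted, gc) {
  b <- clean_cc(random_bases(len, gc))
  for (o in planted) b <- plant_cc_site(b, o)
  paste0(b, collapse = "")
}

# occurrences of seed+PAM (N wildcard) on both strands; gregexpr-based,
# independent of the matchPattern path used by count_binding_sites
scan_pattern_truth <- function(genome, seed, pam = "NGG") {
  pat <- paste0(seed, pam)
  m <- nchar(pat)
  total <- 0L
  for (rec in genome) {
    L <- nchar(rec$seq)
    s <- if (rec$circular) paste0(rec$seq, substr(rec$seq, 1L, m - 1L)) else rec$seq
    for (q in c(pat, revcomp(pat))) {
      re <- gsub("N", "[ACGT]", q)
      hits <- gregexpr(paste0("(?=", re, ")"), s, perl = TRUE)[[1L]]
      if (hits[1L] != -1L) total <- total + sum(hits <= L)
    }
  }
  total
}

# candidate offsets a naive scan would find in a sense sequence (default rules)
scan_cc_offsets <- function(sense, spacer_len = 20L) {
  b <- chars(sense)
  n <- length(b)
  lim <- n - (spacer_len + 3L)
  if (lim < 0L) return(integer(0))
  i <- 0:lim
  i[b[i + 1L] == "C" & b[i + 2L] == "C"]
}

#' Generate a synthetic fixture genome, annotation, and truth table
#'
#' Deterministic for a given spec and seed. The truth table records, per
#' feature, the exact candidate offsets and counts; per planted off-target,
#' the exact genome-wide binding-site count; and the expected censuses.
#' Generation is re-verified by an internal scan and retried (bounded by
#' `max_retries`) if a random background collision slipped through.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory: writes `fixture.fasta`,
#'   `fixture.gff3`, `truth.json`.
#' @return List: `genome` (list of [genome_record()]), `features`
#'   (data.frame), `truth` (list), and `paths` when `dir` is given.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    for (attempt in seq_len(spec$max_retries)) {
      fx <- try_generate(spec)
      if (!is.null(fx)) break
      fx <- NULL
    }
    if (is.null(fx))
      stop(sprintf("fixture spec infeasible after %d attempts", spec$max_retries))
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(fasta = file.path(dir, "fixture.fasta"),
                    gff3 = file.path(dir, "fixture.gff3"),
                    truth = file.path(dir, "truth.json"))
      write_fasta(fx$genome, paths$fasta)
      write_gff3(fx$features, paths$gff3)
      jsonlite::write_json(fx$truth, paths$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      fx$paths <- paths
    }
    fx
  })
}

try_generate <- function(spec) {
  table <- codon_table_11()
  genes <- spec$genes %||% data.frame(id = character(0), length = integer(0),
                                      strand = character(0),
                                      operon_id = character(0),
                                      operon_index = integer(0),
                                      stringsAsFactors = FALSE)
  srnas <- spec$srnas %||% data.frame(id = character(0), length = integer(0),
                                      strand = character(0),
                                      targetable = logical(0),
                                      stringsAsFactors = FALSE)
  pp <- spec$planted_pams %||% data.frame(feature_id = character(0),
                                          offset = integer(0))
  # auto-plant one site per targetable sRNA
  srna_plants <- list()
  for (i in seq_len(nrow(srnas))) {
    s <- srnas[i, ]
    if (isTRUE(s$targetable)) {
      if (s$length < 23L) return(NULL)   # infeasible: cannot be targetable
      o <- sample(0:(s$length - 23L), 1L)
      srna_plants[[length(srna_plants) + 1L]] <-
        data.frame(feature_id = s$id, offset = o)
    }
  }
  plants <- rbind(pp, do.call(rbind, srna_plants) %||%
                    data.frame(feature_id = character(0), offset = integer(0)))

  # feature sense sequences
  sense <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    po <- plants$offset[plants$feature_id == g$id]
    sense[[g$id]] <- gen_cds_sense(g$length, po, spec$gc, table)
  }
  for (i in seq_len(nrow(srnas))) {
    s <- srnas[i, ]
    po <- plants$offset[plants$feature_id == s$id]
    sense[[s$id]] <- gen_srna_sense(s$length, po, spec$gc)
  }

  # layout on record 1: gap, feature, gap, ..., tail padding
  feat <- rbind(
    if (nrow(genes)) data.frame(id = genes$id, length = genes$length,
                                strand = genes$strand, ftype = "CDS",
                                operon_id = genes$operon_id,
                                operon_index = genes$operon_index,
                                stringsAsFactors = FALSE),
    if (nrow(srnas)) data.frame(id = srnas$id, length = srnas$length,
                                strand = srnas$strand, ftype = "sRNA",
                                operon_id = srnas$id, operon_index = 0L,
                                stringsAsFactors = FALSE))
  n_feat <- nrow(feat)
  total_feat <- sum(feat$length)
  slack <- spec$record_length - total_feat
  gaps <- rep(slack %/% (n_feat + 1L), n_feat + 1L)
  gaps[n_feat + 1L] <- gaps[n_feat + 1L] + slack %% (n_feat + 1L)

  pieces <- character(0); starts <- integer(n_feat)
  pos <- 0L
  for (i in seq_len(n_feat)) {
    gap <- paste0(random_bases(gaps[i], spec$gc), collapse = "")
    pieces <- c(pieces, gap); pos <- pos + gaps[i]
    starts[i] <- pos
    gseq <- sense[[feat$id[i]]]
    if (feat$strand[i] == "-") gseq <- revcomp(gseq)
    pieces <- c(pieces, gseq); pos <- pos + feat$length[i]
  }
  pieces <- c(pieces, paste0(random_bases(gaps[n_feat + 1L], spec$gc),
                             collapse = ""))
  rec1 <- paste0(pieces, collapse = "")

  records <- list(genome_record("rec1", rec1, spec$circular))
  if (spec$n_records > 1L) {
    for (r in 2:spec$n_records) {
      records[[r]] <- genome_record(
        paste0("rec", r),
        paste0(random_bases(spec$record_length, spec$gc), collapse = ""),
        spec$circular)
    }
  }

  features <- data.frame(
    id = feat$id, record_id = "rec1", start = starts,
    end = starts + feat$length, strand = feat$strand, ftype = feat$ftype,
    operon_id = feat$operon_id, operon_index = feat$operon_index,
    non_triplet = FALSE, stringsAsFactors = FALSE)

  # planted candidate patterns (seed+PAM instance text on the plus strand)
  plant_info <- list()
  for (i in seq_len(nrow(plants))) {
    fid <- plants$feature_id[i]; o <- plants$offset[i]
    f <- features[features$id == fid, ]
    sseq <- sense[[fid]]
    spacer <- revcomp(sub0(sseq, o + 3L, o + 23L))
    seed <- substr(spacer, 9L, 20L)
    plant_info[[i]] <- list(feature_id = fid, offset = o, seed = seed,
                            pattern = paste0(seed, "NGG"))
  }

  # off-target copies into background, alternating strands
  ot <- spec$offtarget_copies
  copy_records <- records
  ot_truth <- list()
  if (!is.null(ot) && nrow(ot)) {
    free_rec <- if (spec$n_records > 1L) length(copy_records) else 1L
    cursor <- if (free_rec == 1L) {
      # use the tail gap of record 1
      spec$record_length - gaps[n_feat + 1L] + 10L
    } else 10L
    for (i in seq_len(nrow(ot))) {
      match_i <- which(vapply(plant_info, function(p)
        p$feature_id == ot$feature_id[i] & p$offset == ot$offset[i], TRUE))
      if (!length(match_i)) abort_input("offtarget_copies refers to an unplanted site")
      p <- plant_info[[match_i]]
      instance <- paste0(substr(p$pattern, 1L, 12L),
                         sample(c("A", "C", "G", "T"), 1L), "GG")
      for (cp in seq_len(ot$copies[i])) {
        txt <- if (cp %% 2L == 1L) instance else revcomp(instance)
        rec <- copy_records[[free_rec]]
        if (cursor + 15L > nchar(rec$seq)) return(NULL)
        s <- rec$seq
        substr(s, cursor + 1L, cursor + 15L) <- txt
        copy_records[[free_rec]]$seq <- s
        cursor <- cursor + 20L
      }
      ot_truth[[length(ot_truth) + 1L]] <-
        list(feature_id = p$feature_id, offset = p$offset,
             expected_count = ot$copies[i] + 1L)
    }
  }
  records <- copy_records

  # --- verification against the planted truth ---
  for (i in seq_len(n_feat)) {
    f <- features[i, ]
    exp_off <- sort(plants$offset[plants$feature_id == f$id])
    got <- sort(scan_cc_offsets(sense[[f$id]]))
    if (!identical(as.integer(got), as.integer(exp_off))) return(NULL)
  }
  for (p in plant_info) {
    expected <- 1L
    for (t in ot_truth)
      if (t$feature_id == p$feature_id && t$offset == p$offset)
        expected <- t$expected_count
    if (scan_pattern_truth(records, p$seed) != expected) return(NULL)
  }

  targetable <- vapply(features$id, function(fid)
    any(plants$feature_id == fid), TRUE)
  truth <- list(
    per_feature = data.frame(
      feature_id = features$id,
      n_candidates = vapply(features$id, function(fid)
        sum(plants$feature_id == fid), 0L),
      best_dist5 = vapply(features$id, function(fid) {
        o <- plants$offset[plants$feature_id == fid]
        if (length(o)) as.integer(min(o)) else NA_integer_
      }, 0L),
      targetable = targetable,
      stringsAsFactors = FALSE),
    offtargets = ot_truth,
    census = list(n_targetable = sum(targetable), n_total = n_feat),
    srna_census = list(
      n_targetable = sum(targetable[features$ftype == "sRNA"]),
      n_total = sum(features$ftype == "sRNA")))
  rownames(truth$per_feature) <- NULL
  list(genome = records, features = features, truth = truth)
}
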