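# Synonymous "escape" alleles: recode the guide's target site inside a CDS
# so the sgRNA no longer pairs (or loses its PAM) while the protein stays
# identical, allowing complementation of a silenced gene under CRISPRi.

# sense-coordinate windows (0-based half-open) covered by a candidate's
# protospacer/PAM inside its feature, independent of genomic strand
guide_sense_windows <- function(candidate, params = design_params()) {
  i <- candidate$dist5
  sp <- params$spacer_len
  if (!isTRUE(candidate$on_template)) {
    proto <- c(i + 3L, i + 3L + sp)
    pam <- c(i, i + 3L)
    # spacer 3' (PAM-proximal) end maps to the start of the sense slice
    seed <- c(i + 3L, i + 3L + params$seed_len)
    core7 <- c(i + 3L, i + 3L + params$exact_core_len)
    pam_gg <- c(i, i + 1L)          # sense CC encodes the template-strand GG
    pam_gg_char <- "C"
  } else {
    proto <- c(i, i + sp)
    pam <- c(i + sp, i + sp + 3L)
    seed <- c(i + sp - params$seed_len, i + sp)
    core7 <- c(i + sp - params$exact_core_len, i + sp)
    pam_gg <- c(i + sp + 1L, i + sp + 2L)
    pam_gg_char <- "G"
  }
  list(proto = proto, pam = pam, seed = seed, core7 = core7,
       region = c(min(proto[1], pam[1]), max(proto[2], pam[2])),
       pam_gg = pam_gg, pam_gg_char = pam_gg_char)
}

in_window <- function(pos0, w) pos0 >= w[1] & pos0 < w[2]

#' Map a guide's footprint onto the codons of its target CDS
#'
#' @param feature One-row CDS feature data.frame (triplet length).
#' @param candidate One-row candidate data.frame targeting that feature.
#' @param params [design_params()].
#' @return Data.frame with one row per codon overlapping the
#'   protospacer+PAM region: `codon_index` (0-based from the start codon),
#'   `overlap_nt`, `in_seed`, `in_core7`, `in_pam`, and `immutable` (start
#'   and stop codons are never recoded).
#' @export
map_guide_to_codons <- function(feature, candidate, params = design_params()) {
  if (feature$ftype != "CDS")
    abort_input(sprintf("feature %s is not a CDS", feature$id))
  flen <- feature$end - feature$start
  if (flen %% 3L != 0L)
    abort_input(sprintf("CDS %s length not divisible by 3", feature$id))
  if (!identical(candidate$feature_id, feature$id))
    abort_input("candidate does not target this feature")
  w <- guide_sense_windows(candidate, params)
  if (w$region[1] < 0L || w$region[2] > flen)
    abort_input("candidate footprint outside the feature")
  n_codons <- flen %/% 3L
  first <- w$region[1] %/% 3L
  last <- (w$region[2] - 1L) %/% 3L
  idx <- first:last
  res <- lapply(idx, function(j) {
    cw <- c(3L * j, 3L * j + 3L)
    pos <- cw[1]:(cw[2] - 1L)
    data.frame(
      codon_index = j,
      overlap_nt = sum(in_window(pos, w$region)),
      in_seed = any(in_window(pos, w$seed)),
      in_core7 = any(in_window(pos, w$core7)),
      in_pam = any(in_window(pos, w$pam)),
      immutable = j == 0L || j == n_codons - 1L)
  })
  do.call(rbind, res)
}

syn_codons <- function(codon, table) {
  aa <- table$code[[codon]]
  alts <- names(table$code)[table$code == aa]
  setdiff(alts, codon)
}

#' Design synonymous escape alleles for a guide target
#'
#' Enumerates combinations of synonymous single-codon substitutions over
#' the codons overlapping the guide's seed (and PAM), up to
#' `max_codon_changes` codons at a time, and keeps every allele that either
#' changes at least `min_codon_changes` codons or synonymously destroys
#' the PAM's GG. The default of two recoded codons in the PAM-proximal
#' core is the robust recommendation; `min_codon_changes = 1` permits
#' single-codon escapes (a single proline codon change can fully abolish
#' silencing). Start and stop codons are never touched. Every emitted
#' allele is verified protein-identical.
#'
#' @param feature One-row CDS feature data.frame.
#' @param candidate One-row candidate data.frame targeting that feature.
#' @param cds_seq The feature's sense-strand CDS sequence.
#' @param min_codon_changes Minimum number of recoded codons (default 2).
#' @param table Codon table, see [codon_table_11()].
#' @param max_codon_changes Upper bound on recoded codons per allele.
#' @param params [design_params()].
#' @return Data.frame of alleles ordered by (core-7 changes desc, codons
#'   changed desc, total nt changes asc): `feature_id`, `spacer`,
#'   `n_changed_codons`, `changed_codons` ("idx:OLD>NEW;..."),
#'   `nt_changes_in_seed`, `nt_changes_in_core7`, `nt_changes_total`,
#'   `pam_disrupted`, `predicted_strength` ("full"/"partial"),
#'   `mutant_cds`. Zero rows (with a warning) when no synonymous option
#'   exists in the seed.
#' @export
design_escape_alleles <- function(feature, candidate, cds_seq,
                                  min_codon_changes = 2L,
                                  table = codon_table_11(),
                                  max_codon_changes = max(2L, min_codon_changes),
                                  params = design_params()) {
  if (min_codon_changes < 1L) abort_input("min_codon_changes must be >= 1")
  assert_dna(cds_seq, "CDS", allow_n = FALSE)
  flen <- feature$end - feature$start
  if (nchar(cds_seq) != flen || flen %% 3L != 0L)
    abort_input("cds_seq must match the feature and have triplet length")
  cmap <- map_guide_to_codons(feature, candidate, params)
  w <- guide_sense_windows(candidate, params)
  eligible <- cmap[(cmap$in_seed | cmap$in_pam) & !cmap$immutable, , drop = FALSE]
  codons0 <- substring(cds_seq, seq(1L, flen, 3L), seq(3L, flen, 3L))
  options <- lapply(eligible$codon_index, function(j) {
    alts <- syn_codons(codons0[j + 1L], table)
    if (!length(alts)) return(NULL)
    data.frame(codon_index = j, old = codons0[j + 1L], new = alts,
               stringsAsFactors = FALSE)
  })
  options <- options[!vapply(options, is.null, TRUE)]
  if (!length(options)) {
    warning(sprintf(
      "no synonymous substitution available in the target region of %s",
      feature$id), call. = FALSE)
    return(empty_escape_df())
  }
  opt_idx <- vapply(options, function(o) o$codon_index[1L], 0L)
  alleles <- list()
  for (k in seq_len(min(max_codon_changes, length(options)))) {
    for (sel in utils::combn(length(options), k, simplify = FALSE)) {
      choice_grid <- expand.grid(lapply(sel, function(s)
        seq_len(nrow(options[[s]]))), KEEP.OUT.ATTRS = FALSE)
      for (g in seq_len(nrow(choice_grid))) {
        subs <- do.call(rbind, lapply(seq_along(sel), function(q)
          options[[sel[q]]][choice_grid[g, q], ]))
        alleles[[length(alleles) + 1L]] <-
          build_escape_allele(feature, candidate, cds_seq, codons0, subs,
                              w, table)
      }
    }
  }
  out <- do.call(rbind, alleles)
  keep <- (out$n_changed_codons >= min_codon_changes | out$pam_disrupted) &
    (out$nt_changes_in_seed >= 1L | out$pam_disrupted)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning(sprintf("no escape allele satisfies the constraints for %s",
                    feature$id), call. = FALSE)
    return(empty_escape_df())
  }
  o <- order(-out$nt_changes_in_core7, -out$n_changed_codons,
             out$nt_changes_total, out$mutant_cds)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_escape_df <- function() {
  data.frame(feature_id = character(0), spacer = character(0),
             n_changed_codons = integer(0), changed_codons = character(0),
             nt_changes_in_seed = integer(0), nt_changes_in_core7 = integer(0),
             nt_changes_total = integer(0), pam_disrupted = logical(0),
             predicted_strength = character(0), mutant_cds = character(0),
             stringsAsFactors = FALSE)
}

build_escape_allele <- function(feature, candidate, cds_seq, codons0, subs,
                                w, table) {
  codons <- codons0
  codons[subs$codon_index + 1L] <- subs$new
  mutant <- paste0(codons, collapse = "")
  stopifnot(translate_cds(mutant, table) == translate_cds(cds_seq, table))
  diffs <- which(chars(mutant) != chars(cds_seq)) - 1L   # 0-based sense
  seed_codons_changed <- sum(vapply(subs$codon_index, function(j)
    any(in_window((3L * j):(3L * j + 2L), w$seed)), TRUE))
  pam_disrupted <- any(diffs %in% w$pam_gg)
  n_core7 <- sum(in_window(diffs, w$core7))
  n_seed <- sum(in_window(diffs, w$seed))
  strength <- if (seed_codons_changed >= 2L || pam_disrupted || n_core7 >= 1L)
    "full" else "partial"
  data.frame(
    feature_id = feature$id,
    spacer = candidate$spacer,
    n_changed_codons = nrow(subs),
    changed_codons = paste(sprintf("%d:%s>%s", subs$codon_index,
                                   subs$old, subs$new), collapse = ";"),
    nt_changes_in_seed = n_seed,
    nt_changes_in_core7 = n_core7,
    nt_changes_total = length(diffs),
    pam_disrupted = pam_disrupted,
    predicted_strength = strength,
    mutant_cds = mutant,
    stringsAsFactors = FALSE)
}

#' Verify that a recoded CDS escapes its guide
#'
#' Re-extracts the protospacer instance from the mutant CDS and re-applies
#' the pairing rule and the PAM check. Escape succeeds iff pairing fails
#' (run below `min_pairing_run`) or the PAM's GG is destroyed.
#'
#' @param candidate One-row candidate data.frame.
#' @param mutant_cds Recoded CDS (same length as the original; indels are
#'   not supported).
#' @param original_cds Optional original CDS, enabling the per-region
#'   change counts and the protein-identity check in the report.
#' @param params [design_params()].
#' @return List: `escaped`, `pairing_pass`, `run`, `pam_intact`,
#'   `nt_changes` (seed/core7/pam/protospacer/outside; `NA` without the
#'   original), `protein_identical`.
#' @export
verify_escape <- function(candidate, mutant_cds, original_cds = NULL,
                          params = design_params()) {
  assert_dna(mutant_cds, "mutant CDS", allow_n = FALSE)
  if (!is.null(original_cds) && nchar(original_cds) != nchar(mutant_cds))
    abort_input("mutant and original CDS differ in length (indels unsupported)")
  w <- guide_sense_windows(candidate, params)
  if (w$region[2] > nchar(mutant_cds))
    abort_input("candidate footprint outside the mutant CDS")
  site_sense <- sub0(mutant_cds, w$proto[1], w$proto[2])
  site_seq <- if (!isTRUE(candidate$on_template)) revcomp(site_sense) else site_sense
  pairing <- validate_pairing(candidate$spacer, site_seq, params)
  gg <- chars(sub0(mutant_cds, w$pam_gg[1], w$pam_gg[2] + 1L))[c(1L, 2L)]
  pam_intact <- all(gg == w$pam_gg_char)
  nt_changes <- list(seed = NA_integer_, core7 = NA_integer_,
                     pam = NA_integer_, protospacer = NA_integer_,
                     outside = NA_integer_)
  protein_identical <- NA
  if (!is.null(original_cds)) {
    diffs <- which(chars(mutant_cds) != chars(original_cds)) - 1L
    nt_changes <- list(seed = sum(in_window(diffs, w$seed)),
                       core7 = sum(in_window(diffs, w$core7)),
                       pam = sum(in_window(diffs, w$pam)),
                       protospacer = sum(in_window(diffs, w$proto)),
                       outside = sum(!in_window(diffs, w$region)))
    protein_identical <- identical(translate_cds(mutant_cds),
                                   translate_cds(original_cds))
  }
  list(escaped = !pairing$pass || !pam_intact,
       pairing_pass = pairing$pass, run = pairing$run,
       pam_intact = pam_intact, nt_changes = nt_changes,
       protein_identical = protein_identical)
}

#' List the nucleotide substitutions of an escape allele
#'
#' @param original_cds,mutant_cds Equal-length CDS sequences.
#' @return Data.frame `pos` (1-based within the CDS), `ref`, `alt`.
#' @export
escape_variants <- function(original_cds, mutant_cds) {
  if (nchar(original_cds) != nchar(mutant_cds))
    abort_input("sequences differ in length")
  a <- chars(original_cds); b <- chars(mutant_cds)
  d <- which(a != b)
  data.frame(pos = d, ref = a[d], alt = b[d], stringsAsFactors = FALSE)
}

#' Write escape alleles as TSV
#' @param alleles Data.frame from [design_escape_alleles()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_escape_tsv <- function(alleles, path) {
  write_commented_tsv(
    alleles, path,
    c("crisprikit escape alleles (synonymous recodings of the guide target site)",
      "codon indices 0-based from the start codon; nt counts within the guide footprint",
      "predicted_strength: coarse label, not a quantitative model"))
}

#' Write mutant CDS sequences as FASTA
#' @param alleles Data.frame from [design_escape_alleles()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_escape_fasta <- function(alleles, path) {
  if (nrow(alleles) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(alleles$mutant_cds)
  names(set) <- sprintf("%s_escape_%02d|%s", alleles$feature_id,
                        seq_len(nrow(alleles)),
                        gsub(";", ",", alleles$changed_codons))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
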