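#' Construct a genome record
#'
#' A genome record is one replicon: an identifier, an uppercase DNA sequence
#' over \{A,C,G,T,N\}, and a circularity flag. Scanning operations may wrap
#' the origin only when `circular = TRUE`; annotated features never wrap.
#'
#' @param id Replicon identifier.
#' @param seq DNA sequence (coerced to uppercase; `U` is converted to `T`;
#'   IUPAC ambiguity codes other than `N` collapse to `N` with a warning).
#' @param circular Logical, whether the replicon is circular. Default linear.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, seq, circular = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_input("record id must be a non-empty string")
  seq <- normalize_dna(seq)
  if (!nzchar(seq)) abort_input(sprintf("record '%s' has an empty sequence", id))
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "genome_record")
}

# uppercase, U->T, non-ACGTN IUPAC codes -> N (warned); anything else errors
normalize_dna <- function(seq) {
  seq <- toupper(as.character(seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (grepl("[^ACGTN]", seq)) {
    other <- gsub("[ACGTN]", "", seq)
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    bad <- setdiff(unique(chars(other)), iupac)
    if (length(bad))
      abort_input(sprintf("illegal sequence characters: %s",
                          paste(bad, collapse = "")))
    warning(sprintf("ambiguity codes (%s) collapsed to N",
                    paste(unique(chars(other)), collapse = "")),
            call. = FALSE)
    seq <- gsub("[RYSWKMBDHV]", "N", seq)
  }
  seq
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read a (multi-)FASTA genome
#'
#' @param path Path to a FASTA file.
#' @param circular Logical scalar applied to all records, or a character
#'   vector of record ids to mark circular.
#' @return A list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_io(conditionMessage(e)))
  if (length(set) == 0L) abort_input(sprintf("empty FASTA: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    abort_input(sprintf("duplicate record ids in %s: %s", path,
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  circ <- if (is.character(circular)) ids %in% circular
          else rep(isTRUE(circular), length(ids))
  mapply(function(id, s, ci) genome_record(id, s, ci),
         ids, as.character(set), circ,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write genome records to FASTA
#'
#' @param genome A list of [genome_record()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(vapply(genome, `[[`, "", "seq"))
  names(set) <- vapply(genome, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

get_record <- function(genome, id) {
  ids <- vapply(genome, `[[`, "", "id")
  i <- match(id, ids)
  if (is.na(i)) abort_input(sprintf("record '%s' not in genome (%s)",
                                    id, paste(ids, collapse = ", ")))
  genome[[i]]
}

record_ids <- function(genome) vapply(genome, `[[`, "", "id")

#' Read feature annotation from GFF3
#'
#' Converts GFF3's 1-based inclusive coordinates to the package-internal
#' 0-based half-open convention and validates each feature against the
#' genome. Feature type is taken from the GFF3 `type` column (`CDS` and
#' `sRNA`/`ncRNA` are recognised; everything else becomes `other`). Operon
#' structure is read from the optional `operon_id` / `operon_index`
#' attributes; features lacking them are treated as monocistronic
#' (operon_id = own id, operon_index = 0). A CDS whose length is not a
#' multiple of 3 is flagged (`non_triplet`), not rejected.
#'
#' @param path GFF3 file.
#' @param genome List of [genome_record()] objects the features annotate.
#' @return A data.frame with columns `id`, `record_id`, `start`, `end`
#'   (0-based half-open), `strand`, `ftype`, `operon_id`, `operon_index`,
#'   `non_triplet`.
#' @export
read_gff3 <- function(path, genome) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) abort_io(conditionMessage(e)))
  if (length(gr) == 0L)
    return(empty_feature_df())
  mc <- S4Vectors::mcols(gr)
  ids <- as.character(mc$ID)
  if (any(is.na(ids) | !nzchar(ids)))
    abort_input("every GFF3 feature needs an ID attribute")
  if (anyDuplicated(ids))
    abort_input(sprintf("duplicate feature ids: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    abort_input("feature strand must be '+' or '-'")
  type <- as.character(mc$type)
  ftype <- ifelse(type == "CDS", "CDS",
           ifelse(type %in% c("sRNA", "ncRNA"), "sRNA", "other"))
  feats <- data.frame(
    id = ids,
    record_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    ftype = ftype,
    operon_id = if (!is.null(mc$operon_id)) as.character(mc$operon_id)
                else NA_character_,
    operon_index = if (!is.null(mc$operon_index))
                     suppressWarnings(as.integer(as.character(mc$operon_index)))
                   else NA_integer_,
    stringsAsFactors = FALSE)
  no_op <- is.na(feats$operon_id)
  feats$operon_id[no_op] <- feats$id[no_op]
  feats$operon_index[is.na(feats$operon_index)] <- 0L
  validate_features(feats, genome)
}

empty_feature_df <- function() {
  data.frame(id = character(0), record_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             ftype = character(0), operon_id = character(0),
             operon_index = integer(0), non_triplet = logical(0),
             stringsAsFactors = FALSE)
}

validate_features <- function(feats, genome) {
  lens <- stats::setNames(vapply(genome, function(r) nchar(r$seq), 0L),
                          record_ids(genome))
  unknown <- setdiff(feats$record_id, names(lens))
  if (length(unknown))
    abort_input(sprintf("features reference unknown records: %s",
                        paste(unknown, collapse = ", ")))
  bad <- feats$start < 0L | feats$start >= feats$end |
    feats$end > lens[feats$record_id]
  if (any(bad))
    abort_input(sprintf("feature(s) out of bounds: %s",
                        paste(feats$id[bad], collapse = ", ")))
  feats$non_triplet <- feats$ftype == "CDS" & (feats$end - feats$start) %% 3L != 0L
  if (any(feats$non_triplet))
    warning(sprintf("CDS length not divisible by 3, flagged: %s",
                    paste(feats$id[feats$non_triplet], collapse = ", ")),
            call. = FALSE)
  feats
}

#' Write features to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates go out
#' as 1-based inclusive.
#'
#' @param features Feature data.frame (see [read_gff3()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(features, path) {
  type <- ifelse(features$ftype == "sRNA", "ncRNA",
          ifelse(features$ftype == "CDS", "CDS", "region"))
  gr <- GenomicRanges::GRanges(
    seqnames = features$record_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- features$id
  S4Vectors::mcols(gr)$operon_id <- features$operon_id
  S4Vectors::mcols(gr)$operon_index <- features$operon_index
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reverse complement
#'
#' @param seq Character vector of DNA strings over \{A,C,G,T,N\}.
#' @return Reverse complement(s); `N` maps to `N`.
#' @export
revcomp <- function(seq) {
  assert_dna(seq, "revcomp input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Bacterial codon table (translation table 11)
#'
#' @return A list with `code` (named vector, codon to amino acid, 64 entries)
#'   and `starts` (the bacterial initiation codons ATG, GTG, TTG).
#' @export
codon_table_11 <- function() {
  list(code = Biostrings::getGeneticCode("11"),
       starts = c("ATG", "GTG", "TTG"))
}

#' Translate a CDS under the bacterial genetic code
#'
#' Codons are translated exactly per table 11; the initiator codon is not
#' forced to methionine. A terminal stop is reported as `*`; an internal
#' stop is an error.
#'
#' @param cds_seq DNA string, length divisible by 3, no `N`.
#' @param table Codon table, see [codon_table_11()].
#' @return Protein string.
#' @export
translate_cds <- function(cds_seq, table = codon_table_11()) {
  assert_dna(cds_seq, "CDS", allow_n = FALSE)
  if (nchar(cds_seq) == 0L || nchar(cds_seq) %% 3L != 0L)
    abort_input("CDS length must be a positive multiple of 3")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq),
    genetic.code = table$code, no.init.codon = TRUE))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1L]]
  if (stops[1L] != -1L && any(stops < nchar(aa)))
    abort_input("internal stop codon in CDS")
  aa
}

#' Extract a feature's sense-strand sequence
#'
#' For a feature on the `-` strand this is the reverse complement of the
#' plus-strand slice, i.e. the sequence of the mRNA (T for U).
#'
#' @param feature One-row feature data.frame.
#' @param genome List of [genome_record()] objects.
#' @return DNA string, 5' to 3' in feature orientation.
#' @export
feature_seq <- function(feature, genome) {
  rec <- get_record(genome, feature$record_id)
  s <- sub0(rec$seq, feature$start, feature$end)
  if (feature$strand == "-") revcomp(s) else s
}
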