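# Guide-swap cloning oligos: each new spacer is introduced into the
# linearized sgRNA expression vector by annealing two complementary 50-nt
# primers (15-nt vector overlap + 20-nt spacer + 15-nt vector overlap) and
# fusing the duplex with the backbone (quick-fusion cloning). The vector
# overlap sequences are properties of the user's backbone and must be
# supplied; no default is shipped.

#' Make a guide-swap oligo pair
#'
#' @param spacer 20-nt guide sequence.
#' @param up15 15-nt overlap with the 5' end of the linearized vector.
#' @param down15 15-nt overlap with the 3' end of the linearized vector.
#' @param spacer_len Expected spacer length.
#' @return List of class `oligo_pair`: `fwd`, `rev` (both 50 nt, mutual
#'   reverse complements), `spacer`, `up15`, `down15`, and `protocol`
#'   metadata (annealing conditions, for the order sheet).
#' @export
make_guide_swap_oligos <- function(spacer, up15, down15, spacer_len = 20L) {
  assert_dna(spacer, "spacer", allow_n = FALSE)
  assert_dna(up15, "up15", allow_n = FALSE)
  assert_dna(down15, "down15", allow_n = FALSE)
  if (nchar(spacer) != spacer_len)
    abort_input(sprintf("spacer must be %d nt (got %d)", spacer_len, nchar(spacer)))
  if (nchar(up15) != 15L || nchar(down15) != 15L)
    abort_input("vector overlaps must be exactly 15 nt")
  fwd <- paste0(up15, spacer, down15)
  structure(list(
    fwd = fwd, rev = revcomp(fwd),
    spacer = spacer, up15 = up15, down15 = down15,
    protocol = paste("anneal equimolar in TEN buffer (10 mM Tris, 1 mM EDTA,",
                     "100 mM NaCl, pH 8): 95 C 5 min, slow-cool to RT")),
    class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat("<oligo_pair>\n  fwd:", x$fwd, "\n  rev:", x$rev, "\n")
  invisible(x)
}

#' Assemble an sgRNA cassette sequence
#'
#' Spacer followed by the sgRNA scaffold. The scaffold is an opaque,
#' user-supplied sequence (backbone-specific); none is bundled.
#'
#' @param spacer Guide sequence.
#' @param scaffold_seq Scaffold sequence (non-empty).
#' @return The cassette string with attribute `scaffold_provenance`.
#' @export
assemble_sgrna_cassette <- function(spacer, scaffold_seq) {
  assert_dna(spacer, "spacer", allow_n = FALSE)
  if (is.null(scaffold_seq) || !nzchar(scaffold_seq))
    abort_input("a scaffold sequence must be supplied (none is shipped)")
  scaffold_seq <- normalize_dna(scaffold_seq)
  structure(paste0(spacer, scaffold_seq),
            scaffold_provenance = sprintf("user-supplied scaffold (%d nt)",
                                          nchar(scaffold_seq)))
}

#' Write oligo pairs as TSV, FASTA, and a plain-text order sheet
#'
#' @param pairs Named list of `oligo_pair` objects (names become oligo
#'   name prefixes).
#' @param path_tsv,path_fasta,path_order Output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_oligo_sheet <- function(pairs, path_tsv = NULL, path_fasta = NULL,
                              path_order = NULL) {
  nm <- names(pairs) %||% sprintf("guide%02d", seq_along(pairs))
  rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(name = paste0(nm[i], c("_fwd", "_rev")),
               sequence = c(p$fwd, p$rev),
               length = c(nchar(p$fwd), nchar(p$rev)),
               stringsAsFactors = FALSE)
  }))
  written <- character(0)
  if (!is.null(path_tsv)) {
    write_commented_tsv(rows, path_tsv,
                        c("crisprikit guide-swap cloning oligos (5'->3')",
                          "structure: 15-nt vector overlap + spacer + 15-nt vector overlap",
                          pairs[[1L]]$protocol))
    written <- c(written, path_tsv)
  }
  if (!is.null(path_fasta)) {
    set <- Biostrings::DNAStringSet(rows$sequence)
    names(set) <- rows$name
    Biostrings::writeXStringSet(set, path_fasta, width = 70L)
    written <- c(written, path_fasta)
  }
  if (!is.null(path_order)) {
    con <- file(path_order, "w")
    writeLines(c("Oligo order sheet (plain text, 5'->3')",
                 sprintf("%-24s %s", rows$name, rows$sequence)), con)
    close(con)
    written <- c(written, path_order)
  }
  invisible(written)
}
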