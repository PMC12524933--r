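# Internal helpers. All sequence coordinates in this package are 0-based
# half-open unless a function's documentation says otherwise (GFF3 I/O is
# 1-based inclusive at the file boundary only).

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open substring
sub0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

gc_frac <- function(seq) {
  b <- chars(seq)
  mean(b %in% c("G", "C"))
}

assert_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    abort_input(sprintf(
      "%s contains characters outside {A,C,G,T%s}: %s",
      what, if (allow_n) ",N" else "",
      paste(unique(gsub(if (allow_n) "[ACGTN]" else "[ACGT]", "", seq[bad])),
            collapse = "")))
  }
  invisible(TRUE)
}

# condition classes so the CLI can map failures to exit codes
abort_input <- function(msg) {
  stop(errorCondition(msg, class = c("crispri_input_error", "error", "condition")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("crispri_io_error", "error", "condition")))
}

# local, restorable RNG scope: fixture generation never perturbs the
# caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

empty_candidate_df <- function() {
  data.frame(
    feature_id = character(0), record_id = character(0),
    spacer = character(0), pam = character(0),
    proto_start = integer(0), proto_end = integer(0),
    pam_strand = character(0), dist5 = integer(0),
    seed = character(0), seed_gc = numeric(0),
    offtarget_count = integer(0), low_gc_flag = logical(0),
    rank = integer(0), on_template = logical(0),
    stringsAsFactors = FALSE)
}

write_commented_tsv <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
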