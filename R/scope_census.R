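# Operon polar-effect scope and PAM-constraint targetability census.
# A dCas9 roadblock inside an operon halts transcription elongation, so
# the target and everything transcribed after it are silenced while genes
# upstream of the block are untouched.

#' Predict the polar knockdown footprint of a guide within its operon
#'
#' @param target_feature Feature id (string) or one-row feature data.frame.
#' @param features Feature data.frame with operon annotation.
#' @return List of class `knockdown_scope`: `target_feature_id`,
#'   `operon_id`, `silenced` (target plus downstream co-operonic genes in
#'   transcription order) and `unaffected_upstream`.
#' @export
knockdown_scope <- function(target_feature, features) {
  tid <- if (is.character(target_feature)) target_feature else target_feature$id
  t <- features[features$id == tid, , drop = FALSE]
  if (nrow(t) != 1L) abort_input(sprintf("unknown target feature: %s", tid))
  members <- features[features$operon_id == t$operon_id, , drop = FALSE]
  if (length(unique(members$strand)) != 1L)
    abort_input(sprintf("operon %s mixes strands", t$operon_id))
  idx <- sort(members$operon_index)
  if (!identical(idx, seq_along(idx) - 1L) && !identical(idx, as.integer(seq_along(idx) - 1L)))
    abort_input(sprintf("operon %s indices not consecutive from 0", t$operon_id))
  members <- members[order(members$operon_index), , drop = FALSE]
  structure(list(
    target_feature_id = t$id,
    operon_id = t$operon_id,
    silenced = members$id[members$operon_index >= t$operon_index],
    unaffected_upstream = members$id[members$operon_index < t$operon_index]),
    class = "knockdown_scope")
}

#' @export
print.knockdown_scope <- function(x, ...) {
  cat(sprintf("<knockdown_scope> %s (operon %s)\n", x$target_feature_id,
              x$operon_id))
  cat("  silenced (polar):", paste(x$silenced, collapse = " -> "), "\n")
  cat("  unaffected upstream:",
      if (length(x$unaffected_upstream))
        paste(x$unaffected_upstream, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' PAM-constraint targetability census over a feature set
#'
#' For each feature (CDS or sRNA alike, with the non-template rule applied
#' relative to the feature's own transcription direction), counts candidate
#' guides and calls the feature targetable when at least one exists. PAM
#' availability is the limiting factor for short features: both protospacer
#' and PAM must fit inside the feature, so anything under
#' `spacer_len + 3` nt (23 nt by default) is untargetable by geometry.
#' The genome-wide uniqueness screen is applied only when
#' `apply_uniqueness = TRUE`.
#'
#' @param features Feature data.frame.
#' @param genome List of [genome_record()] objects.
#' @param params [design_params()].
#' @param apply_uniqueness Also require a surviving unique candidate.
#' @return List of class `census_result`: `per_feature` data.frame
#'   (`feature_id`, `ftype`, `length`, `targetable`, `n_candidates`,
#'   `best_dist5`), `n_targetable`, `n_total`.
#' @export
targetability_census <- function(features, genome, params = design_params(),
                                 apply_uniqueness = FALSE) {
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    cand <- suppressMessages(enumerate_candidates(f, genome, params))
    if (apply_uniqueness && nrow(cand))
      cand <- filter_unique(cand, genome, params)$kept
    data.frame(
      feature_id = f$id, ftype = f$ftype, length = f$end - f$start,
      targetable = nrow(cand) >= 1L, n_candidates = nrow(cand),
      best_dist5 = if (nrow(cand)) min(cand$dist5) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  per_feature <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), ftype = character(0),
               length = integer(0), targetable = logical(0),
               n_candidates = integer(0), best_dist5 = integer(0),
               stringsAsFactors = FALSE)
  structure(list(per_feature = per_feature,
                 n_targetable = sum(per_feature$targetable),
                 n_total = nrow(per_feature)),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("<census_result> %d of %d features targetable\n",
              x$n_targetable, x$n_total))
  invisible(x)
}

#' Write a census as TSV (plus a one-line JSON summary)
#'
#' @param census A `census_result`.
#' @param path TSV path; the JSON summary goes to `sub("\\\\.tsv$", "",
#'   path)` + `"_summary.json"`.
#' @return The TSV path, invisibly.
#' @export
write_census_tsv <- function(census, path) {
  write_commented_tsv(
    census$per_feature, path,
    c("crisprikit targetability census",
      "targetable: >=1 candidate guide (protospacer+PAM inside the feature)",
      "length: nt; best_dist5: nt from the feature 5' end"))
  jsonlite::write_json(
    list(n_targetable = census$n_targetable, n_total = census$n_total),
    paste0(sub("\\.tsv$", "", path), "_summary.json"),
    auto_unbox = TRUE)
  invisible(path)
}
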