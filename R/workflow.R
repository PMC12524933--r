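# Workflow entry points behind the command-line interface. Each run_*()
# function takes a flat configuration list (see read_run_config()), writes
# its reports into config$out_dir, and returns its results invisibly with
# a `status` of "ok" or "empty".

#' Read a run configuration file
#'
#' A flat, human-editable YAML key/value document. Recognised keys:
#' `genome`, `annotation`, `targets` (comma-separated ids or `"all"`),
#' `out_dir`, the [design_params()] fields (`spacer_len`, `seed_len`,
#' `exact_core_len`, `min_pairing_run`, `pam`, `gc_warn_below`,
#' `require_unique`, `strand_rule`), `census_unique`,
#' `escape_min_codon_changes`, `escape_single`, `oligo_up15`,
#' `oligo_down15`, `scaffold`. Values passed in `overrides` (e.g. from CLI
#' flags) win over file values.
#'
#' @param path YAML file, or `NULL` to start from an empty config.
#' @param overrides Named list of overriding values.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) abort_io(sprintf("no such config file: %s", path))
    yaml::read_yaml(path) %||% list()
  }
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  cfg
}

config_params <- function(config) {
  design_params(
    spacer_len = config$spacer_len %||% 20L,
    seed_len = config$seed_len %||% 12L,
    exact_core_len = config$exact_core_len %||% 7L,
    min_pairing_run = config$min_pairing_run %||% 12L,
    pam = config$pam %||% "NGG",
    gc_warn_below = config$gc_warn_below %||% 0.40,
    require_unique = config$require_unique %||% TRUE,
    strand_rule = config$strand_rule %||% "non_template")
}

config_targets <- function(config) {
  t <- config$targets %||% "all"
  if (identical(t, "all")) return("all")
  trimws(strsplit(paste(t, collapse = ","), ",")[[1L]])
}

load_inputs <- function(config) {
  if (is.null(config$genome) || is.null(config$annotation))
    abort_input("config needs 'genome' (FASTA) and 'annotation' (GFF3) paths")
  genome <- read_fasta(config$genome,
                       circular = config$circular %||% FALSE)
  features <- read_gff3(config$annotation, genome)
  list(genome = genome, features = features)
}

run_log_header <- function(config, params) {
  files <- c(config$genome, config$annotation)
  sums <- tools::md5sum(files[file.exists(files)])
  c(sprintf("crisprikit %s", as.character(utils::packageVersion("crisprikit"))),
    sprintf("params: spacer=%d seed=%d core=%d run=%d pam=%s gc_warn<%.2f unique=%s strand=%s",
            params$spacer_len, params$seed_len, params$exact_core_len,
            params$min_pairing_run, params$pam, params$gc_warn_below,
            params$require_unique, params$strand_rule),
    sprintf("input %s md5 %s", names(sums), unname(sums)))
}

prep_out <- function(config) {
  out <- config$out_dir %||% "."
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  out
}

#' Design ranked guides and write guide reports
#'
#' Writes `guides.tsv`, `guides.bed`, `discarded.tsv` and `design.log`
#' into `config$out_dir`.
#'
#' @param config Configuration list, see [read_run_config()].
#' @return Invisibly, the [design_guides()] result with `$status`.
#' @export
run_design <- function(config) {
  inp <- load_inputs(config)
  params <- config_params(config)
  out <- prep_out(config)
  res <- design_guides(inp$features, inp$genome, params,
                       targets = config_targets(config))
  write_guide_tsv(res$guides, file.path(out, "guides.tsv"))
  write_guide_bed(res$guides, file.path(out, "guides.bed"))
  write_guide_tsv(res$discarded, file.path(out, "discarded.tsv"))
  writeLines(c(run_log_header(config, params), res$log),
             file.path(out, "design.log"))
  res$status <- if (nrow(res$guides)) "ok" else "empty"
  invisible(res)
}

#' Run a targetability census and write its reports
#'
#' Writes `census.tsv` and `census_summary.json` into `config$out_dir`.
#' Set `census_unique: true` to also require genome-wide uniqueness.
#'
#' @param config Configuration list.
#' @return Invisibly, the `census_result` with `$status`.
#' @export
run_census <- function(config) {
  inp <- load_inputs(config)
  params <- config_params(config)
  out <- prep_out(config)
  targets <- config_targets(config)
  feats <- if (identical(targets, "all")) inp$features else {
    missing <- setdiff(targets, inp$features$id)
    if (length(missing))
      abort_input(sprintf("unknown target feature(s): %s",
                          paste(missing, collapse = ", ")))
    inp$features[inp$features$id %in% targets, , drop = FALSE]
  }
  census <- targetability_census(feats, inp$genome, params,
                                 apply_uniqueness = isTRUE(config$census_unique))
  write_census_tsv(census, file.path(out, "census.tsv"))
  census$status <- if (census$n_total) "ok" else "empty"
  invisible(census)
}

#' Design escape alleles for the top-ranked guide of each target
#'
#' Writes `escape.tsv`, `escape_mutants.fasta` and `escape_variants.tsv`
#' into `config$out_dir`. `escape_single: true` lowers
#' `min_codon_changes` to 1.
#'
#' @param config Configuration list.
#' @return Invisibly, a list with `alleles` data.frame and `$status`.
#' @export
run_escape <- function(config) {
  inp <- load_inputs(config)
  params <- config_params(config)
  out <- prep_out(config)
  min_ch <- if (isTRUE(config$escape_single)) 1L
            else as.integer(config$escape_min_codon_changes %||% 2L)
  targets <- config_targets(config)
  feats <- inp$features[inp$features$ftype == "CDS" & !inp$features$non_triplet, ,
                        drop = FALSE]
  if (!identical(targets, "all"))
    feats <- feats[feats$id %in% targets, , drop = FALSE]
  alleles <- list(); variants <- list(); warnings_n <- 0L
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    des <- design_guides(f, inp$genome, params)
    if (nrow(des$guides) == 0L) next
    top <- des$guides[des$guides$rank == 1L, ][1L, ]
    cds <- feature_seq(f, inp$genome)
    al <- withCallingHandlers(
      design_escape_alleles(f, top, cds, min_codon_changes = min_ch,
                            params = params),
      warning = function(w) {
        warnings_n <<- warnings_n + 1L
        invokeRestart("muffleWarning")
      })
    if (nrow(al)) {
      alleles[[length(alleles) + 1L]] <- al
      v <- escape_variants(cds, al$mutant_cds[1L])
      v$feature_id <- f$id
      variants[[length(variants) + 1L]] <- v
    }
  }
  alleles <- if (length(alleles)) do.call(rbind, alleles) else empty_escape_df()
  write_escape_tsv(alleles, file.path(out, "escape.tsv"))
  write_escape_fasta(alleles, file.path(out, "escape_mutants.fasta"))
  vtab <- if (length(variants)) do.call(rbind, variants) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               feature_id = character(0), stringsAsFactors = FALSE)
  write_commented_tsv(vtab, file.path(out, "escape_variants.tsv"),
                      "top escape allele substitutions; pos 1-based within the CDS")
  invisible(list(alleles = alleles, n_warnings = warnings_n,
                 status = if (nrow(alleles)) "ok" else "empty"))
}

#' Generate guide-swap cloning oligos for the top-ranked guides
#'
#' Requires `oligo_up15` / `oligo_down15` (the 15-nt vector overlaps) in
#' the config. Writes `oligos.tsv`, `oligos.fasta`, `oligo_order.txt`.
#'
#' @param config Configuration list.
#' @return Invisibly, a list with `pairs` and `$status`.
#' @export
run_oligos <- function(config) {
  if (is.null(config$oligo_up15) || is.null(config$oligo_down15))
    abort_input("oligo design needs 'oligo_up15' and 'oligo_down15' (15-nt vector overlaps)")
  inp <- load_inputs(config)
  params <- config_params(config)
  out <- prep_out(config)
  res <- design_guides(inp$features, inp$genome, params,
                       targets = config_targets(config))
  top <- res$guides[res$guides$rank == 1L, , drop = FALSE]
  pairs <- lapply(seq_len(nrow(top)), function(i)
    make_guide_swap_oligos(top$spacer[i], config$oligo_up15,
                           config$oligo_down15,
                           spacer_len = params$spacer_len))
  names(pairs) <- top$feature_id
  if (length(pairs))
    write_oligo_sheet(pairs, file.path(out, "oligos.tsv"),
                      file.path(out, "oligos.fasta"),
                      file.path(out, "oligo_order.txt"))
  invisible(list(pairs = pairs,
                 status = if (length(pairs)) "ok" else "empty"))
}

#' Generate the demonstration fixture from a config
#'
#' Uses `config$seed` (default 1) and writes the fixture files into
#' `config$out_dir`.
#'
#' @param config Configuration list.
#' @return Invisibly, the [generate_fixture()] result.
#' @export
run_fixture <- function(config) {
  out <- prep_out(config)
  fx <- generate_fixture(demo_fixture_spec(config$seed %||% 1L), dir = out)
  fx$status <- "ok"
  invisible(fx)
}

#' Demonstration fixture specification
#'
#' A compact synthetic study system: a three-gene operon (mimicking an
#' essential-gene operon whose knockdown is polar), two monocistronic
#' genes on mixed strands, and ten sRNAs of which six carry a candidate
#' site and four (including one 20-nt sRNA, too short for protospacer +
#' PAM) do not.
#'
#' @param seed Integer RNG seed.
#' @return A [fixture_spec()].
#' @export
demo_fixture_spec <- function(seed = 1L) {
  genes <- data.frame(
    id = c("opA1", "opA2", "opA3", "monoB", "monoC"),
    length = c(489L, 312L, 225L, 300L, 396L),
    strand = c("+", "+", "+", "-", "+"),
    operon_id = c("opA", "opA", "opA", "monoB", "monoC"),
    operon_index = c(0L, 1L, 2L, 0L, 0L),
    stringsAsFactors = FALSE)
  planted <- data.frame(
    feature_id = c("opA1", "opA1", "opA2", "opA3", "monoB", "monoC"),
    offset = c(30L, 120L, 45L, 60L, 21L, 9L))
  srnas <- data.frame(
    id = sprintf("srna%02d", 1:10),
    length = c(66L, 90L, 120L, 75L, 102L, 60L, 20L, 48L, 81L, 54L),
    strand = rep(c("+", "-"), 5L),
    targetable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  ot <- data.frame(feature_id = "opA1", offset = 120L, copies = 2L)
  fixture_spec(seed, record_length = 8000L, n_records = 2L, gc = 0.36,
               genes = genes, planted_pams = planted,
               offtarget_copies = ot, srnas = srnas)
}
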