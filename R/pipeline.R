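# Pipeline orchestration: deterministic configuration, cross-species
# comparison, standard-format I/O, and the staged runner
# (curate -> find-targets -> degradome-verify -> conserve).

#' Compare a reference species' verified targets against another species
#'
#' The in-memory cross-species stage: finds reciprocal-best-hit homologs of
#' the reference target transcripts, scans the other species' repertoire
#' over its transcriptome and validates the hits, additionally projects each
#' reference site onto its homolog and validates the projected window (so a
#' degraded site still yields a failed candidate — category III feedstock),
#' then classifies every reference pair as category I/II/III/none.
#'
#' @param reference_records Verified reference pairs: tibble with `mirna`
#'   (family), `transcript_id`, `start`, `end`.
#' @param ref_mirnas Tibble `family`, `seq` for the reference repertoire.
#' @param ref_transcripts,other_transcripts Tibbles `id`, `seq`.
#' @param other_mirnas Tibble `family`, `seq` for the other repertoire.
#' @param rules A [target_rules()] object.
#' @param params A [duplex_params()] object.
#' @param scoring An [rbh_scoring()] object.
#' @return A list with `classification` (from [classify_conservation()]),
#'   `rbh`, and `other_sites` (validated and failed candidates on the other
#'   species' transcripts).
#' @export
compare_species <- function(reference_records, ref_mirnas, ref_transcripts,
                            other_mirnas, other_transcripts,
                            rules = target_rules(),
                            params = duplex_params(),
                            scoring = rbh_scoring()) {
  rbh <- reciprocal_best_hits(ref_transcripts, other_transcripts, scoring)

  other_sites <- if (nrow(other_mirnas) > 0L) {
    scanned <- scan_targets(
      tibble::tibble(id = other_mirnas$family, seq = other_mirnas$seq),
      other_transcripts, rules)
    scanned <- validate_sites(scanned,
      tibble::tibble(id = other_mirnas$family, seq = other_mirnas$seq),
      other_transcripts, rules, params)
    dplyr::rename(scanned, mirna = "mirna_id")
  } else {
    tibble::tibble(mirna = character(0), transcript_id = character(0),
                   start = integer(0), end = integer(0),
                   validated = logical(0))
  }

  # project each reference site onto its homolog and validate the window
  homolog_of <- setNames(rbh$id_b[rbh$reciprocal], rbh$id_a[rbh$reciprocal])
  ref_seq <- setNames(ref_transcripts$seq, ref_transcripts$id)
  oth_seq <- setNames(other_transcripts$seq, other_transcripts$id)
  mi_seq <- setNames(ref_mirnas$seq, ref_mirnas$family)
  projected <- purrr::map(seq_len(nrow(reference_records)), function(r) {
    tx <- reference_records$transcript_id[r]
    hom <- homolog_of[tx]
    if (is.na(hom)) return(NULL)
    fam <- reference_records$mirna[r]
    L <- nchar(mi_seq[[fam]])
    p_start <- project_coordinate(ref_seq[[tx]], oth_seq[[hom]],
                                  reference_records$start[r],
                                  scoring = scoring)
    if (is.na(p_start)) return(NULL)
    p_end <- min(p_start + L - 1L, nchar(oth_seq[[hom]]))
    v <- validate_site(mi_seq[[fam]], p_start, p_end, oth_seq[[hom]],
                       rules = rules, params = params)
    tibble::tibble(mirna = fam, transcript_id = unname(hom),
                   start = as.integer(p_start), end = as.integer(p_end),
                   validated = v$validated)
  })
  projected <- dplyr::bind_rows(projected)
  all_sites <- dplyr::bind_rows(
    dplyr::select(other_sites, dplyr::all_of(
      c("mirna", "transcript_id", "start", "end", "validated"))),
    projected)

  classification <- classify_conservation(
    reference_records, rbh, all_sites,
    other_repertoire = unique(other_mirnas$family))
  list(classification = classification, rbh = rbh, other_sites = all_sites)
}

#' Assemble a pipeline configuration
#'
#' A fully serialisable description of one pipeline run: input paths, rule
#' and threshold settings, the RNG seed, and the output directory. The
#' object round-trips bit-exactly through [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param reference Named list with paths `mirnas` (TSV: `id`, `family`,
#'   `seq`), `transcripts` (FASTA), `degradome` (FASTA, optional).
#' @param others List of named lists (`species`, `mirnas`, `transcripts`)
#'   for each non-reference species; may be empty.
#' @param candidates,stacks Optional paths for the curation stage
#'   (candidates TSV with the [make_hairpin()] columns; stacks TSV).
#' @param out_dir Output directory.
#' @param rules,thresholds,cleavage Named lists of non-default settings
#'   (merged over [target_rules()], [curation_thresholds()],
#'   [cleavage_rule()]).
#' @param rng_seed Integer seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, others = list(),
                            candidates = NULL, stacks = NULL,
                            out_dir = "mirslice-out",
                            rules = list(), thresholds = list(),
                            cleavage = list(), rng_seed = 1L,
                            log_level = "info") {
  structure(list(reference = reference, others = others,
                 candidates = candidates, stacks = stacks,
                 out_dir = out_dir, rules = rules, thresholds = thresholds,
                 cleavage = cleavage, rng_seed = as.integer(rng_seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path A YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

# stable polynomial content hash (mod 2^31 - 1) of the serialized config
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

merge_settings <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

#' Write a site table as BED
#'
#' BED uses 0-based half-open coordinates; all other package output is
#' 1-based inclusive.
#'
#' @param sites Site tibble (`transcript_id`, `start`, `end`, `mirna_id`).
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble::tibble(chrom = sites$transcript_id,
                        chromStart = sites$start - 1L,
                        chromEnd = sites$end,
                        name = sites$mirna_id,
                        score = 0L, strand = "-")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

pipe_log <- function(level, ...) {
  if (identical(level, "quiet")) return(invisible())
  message("[mirslice] ", ...)
}

#' Run the full pipeline from a configuration
#'
#' Executes curate (when candidate inputs are configured), find-targets,
#' degradome-verify (when degradome reads are configured) and conserve (for
#' every configured other species), in order, writing each stage's outputs
#' before the next starts, plus a machine-readable run manifest (package
#' version, config hash, seed). Outputs are fully ordered (transcript id,
#' then coordinate, then miRNA id), so re-running an identical config and
#' seed reproduces byte-identical tables. Logs go to stderr; results to
#' files only.
#'
#' @param config A [pipeline_config()] object (or a path to a YAML config).
#' @return Invisibly, a named list of the result tibbles
#'   (`curation`, `sites`, `verified`, `conservation`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  lv <- config$log_level
  rules <- do.call(target_rules, config$rules)
  thresholds <- do.call(curation_thresholds, config$thresholds)
  clv_rule <- do.call(cleavage_rule, config$cleavage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  results <- list()

  # -- curate ---------------------------------------------------------------
  if (!is.null(config$candidates)) {
    pipe_log(lv, "stage curate: ", config$candidates)
    candidates <- readr::read_tsv(config$candidates, show_col_types = FALSE)
    stacks <- readr::read_tsv(config$stacks, show_col_types = FALSE)
    audit <- curate_mirnas(candidates, stacks, thresholds,
                           seed = config$rng_seed)
    audit <- dplyr::arrange(audit, .data$id)
    readr::write_tsv(audit, out("curation_audit.tsv"))
    results$curation <- audit
  }

  # -- find-targets ---------------------------------------------------------
  ref_mirnas <- readr::read_tsv(config$reference$mirnas,
                                show_col_types = FALSE)
  ref_tx <- read_rna_fasta(config$reference$transcripts)
  pipe_log(lv, "stage find-targets: ", nrow(ref_mirnas), " miRNAs vs ",
           nrow(ref_tx), " transcripts")
  mir_tbl <- tibble::tibble(id = ref_mirnas$family,
                            seq = normalize_rna(ref_mirnas$seq))
  mir_tbl <- dplyr::distinct(mir_tbl)
  sites <- scan_targets(mir_tbl, ref_tx, rules)
  sites <- validate_sites(sites, mir_tbl, ref_tx, rules)
  sites <- dplyr::arrange(sites, .data$transcript_id, .data$start,
                          .data$mirna_id)
  readr::write_tsv(sites, out("target_sites.tsv"))
  write_sites_bed(sites, out("target_sites.bed"))
  results$sites <- sites

  # -- degradome-verify -----------------------------------------------------
  verified_records <- dplyr::filter(sites, .data$validated)
  if (!is.null(config$reference$degradome)) {
    pipe_log(lv, "stage degradome-verify: ", config$reference$degradome)
    dg <- read_rna_fasta(config$reference$degradome)
    mapped <- map_degradome(
      tibble::tibble(read_id = dg$id, seq = dg$seq), ref_tx)
    verified <- verify_sites(dplyr::filter(sites, .data$validated),
                             mapped, clv_rule)
    verified <- dplyr::arrange(verified, .data$transcript_id, .data$start,
                               .data$mirna_id)
    readr::write_tsv(verified, out("verified_targets.tsv"))
    results$verified <- verified
    verified_records <- dplyr::filter(verified, .data$verified)
  }

  # -- conserve -------------------------------------------------------------
  if (length(config$others) > 0L) {
    ref_records <- dplyr::select(
      dplyr::rename(verified_records, mirna = "mirna_id"),
      dplyr::all_of(c("mirna", "transcript_id", "start", "end")))
    ref_rep <- dplyr::distinct(
      tibble::tibble(family = ref_mirnas$family,
                     seq = normalize_rna(ref_mirnas$seq)))
    conservation <- purrr::map(config$others, function(other) {
      pipe_log(lv, "stage conserve: ", other$species)
      o_mirnas <- readr::read_tsv(other$mirnas, show_col_types = FALSE)
      o_tx <- read_rna_fasta(other$transcripts)
      cmp <- compare_species(
        ref_records, ref_rep, ref_tx,
        dplyr::distinct(tibble::tibble(family = o_mirnas$family,
                                       seq = normalize_rna(o_mirnas$seq))),
        o_tx, rules)
      dplyr::mutate(cmp$classification, species = other$species,
                    .before = 1L)
    })
    conservation <- dplyr::bind_rows(conservation)
    conservation <- dplyr::arrange(conservation, .data$species,
                                   .data$transcript_id, .data$mirna)
    readr::write_tsv(conservation, out("conservation.tsv"))
    results$conservation <- conservation
  }

  manifest <- list(package = "mirslice",
                   version = as.character(utils::packageVersion("mirslice")),
                   config_hash = config_hash(config),
                   rng_seed = config$rng_seed)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  pipe_log(lv, "done: ", config$out_dir)
  invisible(results)
}
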