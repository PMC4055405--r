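# On-disk formats: band matrices and call tables as TSV, genotypes as
# BED-like tables (0-based half-open), event logs as JSONL, lineage and
# scenario configurations as YAML, CT tables as TSV, amplicons as FASTA.
# Coordinates are 0-based half-open everywhere on disk and internally;
# human-readable reports are the only place 1-based positions appear.

#' Write / read a band matrix TSV
#'
#' Wide layout: one row per (plant, locus, combo) with one 0/1 column per
#' tissue; tissues not assayed for a plant are empty cells.
#'
#' @param bands Long band tibble (`plant`, `locus_id`, `combo`, `tissue`,
#'   `present`).
#' @param path File path.
#' @return `write_band_tsv()` returns `path` invisibly; `read_band_tsv()`
#'   the long tibble.
#' @export
write_band_tsv <- function(bands, path) {
  wide <- bands |>
    mutate(present = as.integer(.data$present)) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "present")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_band_tsv
#' @export
read_band_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("plant", "locus_id", "combo")
  miss <- setdiff(need, names(wide))
  if (length(miss)) abort(paste0("band TSV lacks column: ", miss[1]))
  tcols <- intersect(sampled_tissues(), names(wide))
  if (!length(tcols)) abort("band TSV has no tissue columns")
  wide |>
    tidyr::pivot_longer(all_of(tcols), names_to = "tissue",
                        values_to = "present", values_drop_na = TRUE) |>
    mutate(present = .data$present > 0)
}

#' Write / read a genotype as a BED-like table
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open; mPing insertion
#' sites are 1-bp features), `locus_id`, `hap`.
#'
#' @param geno Genotype tibble (`chrom`, `pos`, `locus_id`, `hap`, `flank`).
#' @param path File path.
#' @return `write_genotype_bed()` returns `path` invisibly;
#'   `read_genotype_bed()` the genotype tibble.
#' @export
write_genotype_bed <- function(geno, path) {
  bed <- geno |>
    mutate(start = .data$pos, end = .data$pos + 1L) |>
    select("chrom", "start", "end", "locus_id", "hap", any_of("flank"))
  readr::write_tsv(bed, path)
  invisible(path)
}

#' @rdname write_genotype_bed
#' @export
read_genotype_bed <- function(path) {
  bed <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("chrom", "start", "end", "locus_id", "hap"), names(bed))
  if (length(miss)) abort(paste0("BED lacks column: ", miss[1]))
  bed |>
    mutate(pos = as.integer(.data$start)) |>
    select("chrom", "pos", "locus_id", "hap", any_of("flank"))
}

#' Write / read an event log as JSONL
#'
#' One JSON object per line; the affected-tissue set is stored as an array.
#'
#' @param events Event tibble (as in a `plant`'s `events`, optionally with
#'   a `plant` column).
#' @param path File path.
#' @return `write_events_jsonl()` returns `path` invisibly;
#'   `read_events_jsonl()` the tibble.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      rec <- as.list(events[i, setdiff(names(events), "tissues")])
      rec$tissues <- events$tissues[[i]]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                  na = "null"), con)
    }
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(empty_events())
  list_rbind(map(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tiss <- list(as.character(rec$tissues))
    rec$tissues <- NULL
    rec <- map(rec, function(x) if (is.null(x)) NA else x)
    out <- as_tibble(rec)
    out$tissues <- tiss
    out
  }))
}

#' Read a CT table TSV
#'
#' Expected columns: `sample`, `target_ct`, `ref_ct`, `is_calibrator`
#' (0/1 or logical).
#'
#' @param path File path.
#' @return CT tibble suitable for [ddct()].
#' @export
read_ct_tsv <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("sample", "target_ct", "ref_ct", "is_calibrator"), names(ct))
  if (length(miss)) abort(paste0("CT table lacks column: ", miss[1]))
  ct$is_calibrator <- as.logical(ct$is_calibrator)
  ct
}

#' Read a lineage configuration file
#'
#' YAML with top-level `horizon` and `compartments` (list of `name`,
#' `parents`, `birth`, optional `tissue`, optional `gamete_origin`). The
#' shipped default (`system.file("extdata", "lineage_default.yaml",
#' package = "mpingr")`) reproduces the default ontogeny timeline.
#'
#' @param path File path.
#' @return A configuration list for [build_lineage()].
#' @export
read_lineage_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$compartments)) abort("lineage config lacks `compartments`")
  cfg
}

#' Read a scenario configuration file
#'
#' YAML with a `design` field (`ontogeny_cohort`, `reciprocal_f1` or
#' `ag_panel`) plus the design's parameters; see the shipped examples under
#' `system.file("extdata", package = "mpingr")`.
#'
#' @param path File path.
#' @return The configuration list.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design) ||
      !cfg$design %in% c("ontogeny_cohort", "reciprocal_f1", "ag_panel")) {
    abort("scenario config needs design: ontogeny_cohort, reciprocal_f1 or ag_panel")
  }
  cfg
}

#' Write classified calls as TSV
#'
#' @param calls Classified call tibble (from [classify_calls()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  flat <- calls |>
    mutate(
      present_tissues = map_chr(.data$present_tissues,
                                function(x) paste(x %||% character(), collapse = ",")),
      windows = NULL
    )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, configuration hash, seed, inputs/outputs, package
#' version and timestamp of a pipeline run; reruns with equal inputs and
#' seed reproduce the outputs byte for byte (the manifest itself carries the
#' timestamp and is excluded from that guarantee).
#'
#' @param path Output path (JSON).
#' @param command Sub-command name.
#' @param config Configuration list (hashed into the manifest).
#' @param seed Seed used.
#' @param inputs,outputs Character vectors of paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seed = NA,
                           inputs = character(), outputs = character()) {
  manifest <- list(
    command = command,
    config_hash = rlang::hash(config),
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    package = "mpingr",
    version = as.character(utils::packageVersion("mpingr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
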