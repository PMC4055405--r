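# De novo insertion calling against parents, the five-category
# tissue-specificity classification (plus the uncategorized and flagged
# composite rules), timing inference through the lineage model, inheritance
# prediction/measurement, and excision classification.

insertion_categories <- function() {
  c("endosperm", "radicle", "leaf", "shoot", "radicle_shoot",
    "uncategorized", "composite")
}

#' Classify a tissue presence pattern
#'
#' Applies the organ-specificity rules to the set of sampled tissues in
#' which a band appeared:
#' * `endosperm` — only the endosperm sample;
#' * `radicle` — only the radicle sample;
#' * `leaf` — exactly one of the 1st-3rd leaf blades and neither the 4th
#'   nor 5th (an upper-leaf check is what separates leaf- from
#'   shoot-specific events);
#' * `shoot` — at least one of the 1st-3rd and at least one of the 4th/5th
#'   leaf blades, no radicle, no endosperm;
#' * `radicle_shoot` — the radicle plus at least one leaf blade;
#' * `uncategorized` — leaf presence that cannot be confirmed against an
#'   upper leaf (confined to the 4th/5th blades, or several of the 1st-3rd
#'   without a 4th/5th);
#' * `composite` — endosperm plus any embryo tissue, possible only through
#'   a shared gamete lineage and reported separately as a flagged pattern.
#'
#' @param present Character vector of sampled tissues with the band (subset
#'   of [sampled_tissues()]; must be non-empty).
#' @return A single category string.
#' @export
classify_insertion <- function(present) {
  present <- unique(as.character(present))
  bad <- setdiff(present, sampled_tissues())
  if (length(bad)) abort(paste0("unknown tissue in presence set: ", bad[1]))
  if (!length(present)) abort("all-absent presence vector cannot be classified")
  has_e <- "E" %in% present
  has_r <- "R" %in% present
  early <- intersect(present, c("L1", "L2", "L3"))
  late <- intersect(present, c("L4", "L5"))
  n_leaf <- length(early) + length(late)
  if (has_e && length(present) > 1) return("composite")
  if (has_e) return("endosperm")
  if (has_r && n_leaf > 0) return("radicle_shoot")
  if (has_r) return("radicle")
  if (length(early) >= 1 && length(late) >= 1) return("shoot")
  if (length(early) == 1 && length(late) == 0) return("leaf")
  "uncategorized"
}

first_leaf_of <- function(present) {
  leaves <- intersect(c("L1", "L2", "L3", "L4", "L5"), present)
  if (length(leaves)) leaves[1] else NA_character_
}

#' Call de novo insertions against parents
#'
#' A band is a de novo insertion when it appears in exactly one progeny and
#' in no genotyped parent. A band present in every progeny but absent from
#' the genotyped parent(s) is attributed to the other (ungenotyped) parent;
#' a band in two or more (but not all) progeny and absent from the parents
#' is flagged anomalous (it would imply a transmissible event during the
#' parent's vegetative or reproductive phase).
#'
#' @param parent_bands Long band tibble for the genotyped parent(s)
#'   (`plant`, `locus_id`, `combo`, `tissue`, `present`).
#' @param progeny_bands Long band tibble for the progeny cohort (same
#'   schema).
#' @return Tibble with one row per (locus, combo) and columns `locus_id`,
#'   `combo`, `status` (`de_novo`, `ancestral`, `other_parent`, `anomalous`,
#'   `parent_only`), `n_progeny_present`, `plant` (the carrier for de novo
#'   calls) and `present_tissues` (list column, the carrier's presence set).
#' @export
call_de_novo <- function(parent_bands, progeny_bands) {
  need <- c("plant", "locus_id", "combo", "tissue", "present")
  for (d in list(parent_bands, progeny_bands)) {
    miss <- setdiff(need, names(d))
    if (length(miss)) abort(paste0("band matrix lacks column: ", miss[1]))
  }
  shared <- intersect(unique(parent_bands$combo), unique(progeny_bands$combo))
  if (!setequal(unique(progeny_bands$combo), shared) &&
      length(unique(parent_bands$combo))) {
    # combos must be assayed in both generations to be comparable
    parent_bands <- parent_bands[parent_bands$combo %in% shared, ]
    progeny_bands <- progeny_bands[progeny_bands$combo %in% shared, ]
  }
  n_prog <- length(unique(progeny_bands$plant))
  prog_pres <- progeny_bands |>
    filter(.data$present) |>
    distinct(.data$plant, .data$locus_id, .data$combo)
  prog_n <- count(prog_pres, .data$locus_id, .data$combo, name = "n_progeny_present")
  par_pres <- parent_bands |>
    filter(.data$present) |>
    distinct(.data$locus_id, .data$combo) |>
    mutate(in_parent = TRUE)
  all_keys <- distinct(
    bind_rows(select(parent_bands, "locus_id", "combo"),
              select(progeny_bands, "locus_id", "combo")),
    .data$locus_id, .data$combo
  )
  calls <- all_keys |>
    left_join(prog_n, by = c("locus_id", "combo")) |>
    left_join(par_pres, by = c("locus_id", "combo")) |>
    mutate(
      n_progeny_present = dplyr::coalesce(.data$n_progeny_present, 0L),
      in_parent = !is.na(.data$in_parent),
      status = dplyr::case_when(
        in_parent & n_progeny_present > 0 ~ "ancestral",
        in_parent ~ "parent_only",
        n_progeny_present == 1 ~ "de_novo",
        n_progeny_present == n_prog & n_prog > 1 ~ "other_parent",
        n_progeny_present >= 2 ~ "anomalous",
        TRUE ~ "absent"
      )
    ) |>
    filter(.data$status != "absent")
  carriers <- prog_pres |>
    group_by(.data$locus_id, .data$combo) |>
    summarise(plant = if (n() == 1) .data$plant[1] else NA_character_,
              .groups = "drop")
  tiss <- progeny_bands |>
    filter(.data$present) |>
    group_by(.data$plant, .data$locus_id, .data$combo) |>
    summarise(present_tissues = list(intersect(sampled_tissues(),
                                               unique(.data$tissue))),
              .groups = "drop")
  calls |>
    left_join(carriers, by = c("locus_id", "combo")) |>
    left_join(tiss, by = c("plant", "locus_id", "combo")) |>
    select("locus_id", "combo", "status", "n_progeny_present", "plant",
           "present_tissues")
}

#' Classify de novo calls and infer their timing
#'
#' Adds the organ-specificity category, the first leaf carrying the band,
#' the candidate timing windows from the lineage model and the heritability
#' prediction (`TRUE` when some candidate window includes the germline).
#'
#' @param calls Output of [call_de_novo()] (rows with `status == "de_novo"`
#'   are classified; other rows are kept with `NA` category).
#' @param tree A `lineage_tree`.
#' @return `calls` with added columns `category`, `first_leaf`, `windows`
#'   (list of window tibbles), `timing` (label of the windows) and
#'   `heritable_pred`.
#' @export
classify_calls <- function(calls, tree = default_lineage()) {
  res <- calls
  res$category <- NA_character_
  res$first_leaf <- NA_character_
  res$windows <- vector("list", nrow(res))
  res$timing <- NA_character_
  res$heritable_pred <- NA
  idx <- which(res$status == "de_novo")
  for (i in idx) {
    pres <- res$present_tissues[[i]]
    if (is.null(pres) || !length(pres)) next
    res$category[i] <- classify_insertion(pres)
    res$first_leaf[i] <- first_leaf_of(pres)
    w <- candidate_windows(tree, pres)
    res$windows[[i]] <- w
    res$timing[i] <- paste(w$label, collapse = " | ")
    res$heritable_pred[i] <- any(w$heritable)
  }
  res
}

#' Candidate timing for one classified call
#'
#' Thin wrapper over [candidate_windows()] for a single presence set; the
#' windows automatically refine shoot-specific timing so that the upper
#' bound is the split time of the earliest leaf carrying the band.
#'
#' @param present Character vector of sampled tissues with the band.
#' @param tree A `lineage_tree`.
#' @return Window tibble as from [candidate_windows()].
#' @export
infer_timing <- function(present, tree = default_lineage()) {
  candidate_windows(tree, present)
}

#' Inheritance percentage with the reporting convention
#'
#' @param inherited Number of calls re-detected in the next generation.
#' @param detected Number of calls scored.
#' @return List with `fraction` and `percent` (nearest integer percent).
#' @export
score_inheritance <- function(inherited, detected) {
  if (detected <= 0) abort("detected must be > 0")
  if (inherited < 0 || inherited > detected) {
    abort("inherited must lie in [0, detected]")
  }
  frac <- inherited / detected
  list(fraction = frac, percent = round(100 * frac))
}

#' Predict and measure inheritance of de novo insertions
#'
#' Prediction: a call is heritable when some candidate timing window
#' includes the germline. Measurement: a call detected in a parent is
#' inherited when its band appears in at least one of that parent's selfed
#' progeny. Under Mendelian segregation a heterozygous germline insertion is
#' seen in at least one of n progeny with probability 1 - (1/4)^n.
#'
#' @param s1_calls Classified calls (from [classify_calls()]) for the
#'   parents, with `plant` set; only `de_novo` rows are scored.
#' @param s2_bands Long band matrix of the progeny generation.
#' @param pedigree Tibble `plant` (progeny id), `parent` (its parent's id).
#' @return List with `calls` (per-call `inherited` flag) and `by_category`
#'   (detected, inherited, fraction, percent, predicted heritability and
#'   the Mendelian detection probability for the median family size).
#' @export
predict_and_measure_inheritance <- function(s1_calls, s2_bands, pedigree) {
  miss <- setdiff(c("plant", "parent"), names(pedigree))
  if (length(miss)) abort(paste0("pedigree lacks column: ", miss[1]))
  calls <- filter(s1_calls, .data$status == "de_novo", !is.na(.data$plant))
  if (!all(calls$plant %in% pedigree$parent)) {
    calls <- filter(calls, .data$plant %in% pedigree$parent)
  }
  s2_pres <- s2_bands |>
    filter(.data$present) |>
    distinct(.data$plant, .data$locus_id) |>
    left_join(pedigree, by = "plant")
  calls$inherited <- map_lgl(seq_len(nrow(calls)), function(i) {
    any(s2_pres$locus_id == calls$locus_id[i] &
          s2_pres$parent == calls$plant[i])
  })
  fam <- count(pedigree, .data$parent)
  n_med <- if (nrow(fam)) median(fam$n) else NA_real_
  by_cat <- calls |>
    group_by(.data$category) |>
    summarise(
      detected = n(),
      inherited = sum(.data$inherited),
      predicted_heritable = any(.data$heritable_pred),
      .groups = "drop"
    ) |>
    mutate(
      fraction = .data$inherited / .data$detected,
      percent = round(100 * .data$fraction),
      p_detect_mendelian = 1 - (1 / 4)^n_med
    )
  list(calls = calls, by_category = by_cat)
}

#' Classify an excision from SCAR PCR states
#'
#' The excision presence vector is the set of tissues whose PCR state shows
#' an empty allele (`empty` or `both`); it is then classified with the same
#' organ-specificity rules as de novo insertions. All-filled states mean no
#' excision.
#'
#' @param states Named character vector over sampled tissues with values
#'   `"filled"`, `"empty"` or `"both"`.
#' @return A category string, or `"no_excision"`.
#' @export
classify_excision <- function(states) {
  bad <- setdiff(names(states), sampled_tissues())
  if (length(bad)) abort(paste0("unknown tissue: ", bad[1]))
  if (!all(states %in% c("filled", "empty", "both"))) {
    abort("states must be filled/empty/both")
  }
  present <- names(states)[states %in% c("empty", "both")]
  if (!length(present)) return("no_excision")
  classify_insertion(present)
}

#' Survey excisions across assayed marker loci
#'
#' Runs [locus_pcr()] for each marker over the sampled tissues of a plant
#' and classifies the excision pattern of each locus.
#'
#' @param plant A `plant`.
#' @param loci Marker locus ids (default: all baseline loci of the plant).
#' @param tissues Sampled tissues to assay.
#' @param detection_fraction Passed to [locus_pcr()].
#' @return Tibble `locus_id`, `category`, plus one state column per tissue.
#' @export
survey_excisions <- function(plant, loci = NULL,
                             tissues = sampled_tissues(),
                             detection_fraction = 0.1) {
  loci <- loci %||% unique(plant$zygote$locus_id)
  rows <- map(loci, function(lc) {
    st <- setNames(
      map_chr(tissues, function(tt) {
        locus_pcr(plant, tt, lc, detection_fraction = detection_fraction)
      }),
      tissues
    )
    c(list(locus_id = lc, category = classify_excision(st)), as.list(st))
  })
  list_rbind(map(rows, as_tibble))
}
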