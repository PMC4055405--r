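# In-silico assays: transposon display (TD) with two selective bases,
# locus-specific SCAR PCR for excision detection, CAPS digestion for the
# Ping +1261 C/T SNP, 2^-ddCt relative expression, and copy-number qPCR.

#' The 16 selective primer combinations
#'
#' TD amplifies mPing-flank junctions; a two-base selective extension on the
#' adapter primer splits the loci into 16 bins, one per dinucleotide.
#'
#' @return Tibble with column `combo` (16 dinucleotides).
#' @export
primer_combos <- function() {
  bases <- c("A", "C", "G", "T")
  tibble(combo = as.vector(outer(bases, bases, paste0)))
}

#' Transposon display of one tissue
#'
#' A band is scored for (locus, combo) when the locus's 2-bp flank equals
#' the combo's selective bases and the event's cell fraction in the tissue
#' is at or above the detection fraction. Scoring is dosage-blind:
#' homozygous and heterozygous insertions give the same band.
#'
#' @param plant A `plant`.
#' @param tissue A sampled tissue label.
#' @param combos Tibble of primer combos (default all 16).
#' @param detection_fraction Minimum cell fraction for a visible band.
#' @return Tibble `locus_id`, `combo`, `tissue`, `present` (only bands that
#'   are present; see [cohort_band_matrix()] for completed matrices).
#' @export
transposon_display <- function(plant, tissue, combos = primer_combos(),
                               detection_fraction = 0.1) {
  if (!tissue %in% sampled_tissues()) abort(paste0("unknown tissue: ", tissue))
  geno <- tissue_genotype(plant, tissue)
  geno <- geno[geno$fraction >= detection_fraction, ]
  geno |>
    distinct(.data$locus_id, .data$flank) |>
    rename(combo = "flank") |>
    semi_join(combos, by = "combo") |>
    mutate(tissue = tissue, present = TRUE)
}

#' Band matrix of a cohort
#'
#' Runs TD over the sampled tissues of each plant and completes the result
#' to a long presence/absence matrix over every (locus, combo) seen in the
#' cohort or in the supplied parents. Tissues not sampled for a plant are
#' absent from the output (missing, not scored).
#'
#' @param plants Named list of `plant` objects.
#' @param tissues Character vector of tissues to assay, or a named list
#'   giving the tissues per plant.
#' @param combos Primer combos to run.
#' @param detection_fraction Passed to [transposon_display()].
#' @return Long tibble `plant`, `locus_id`, `combo`, `tissue`, `present`.
#' @export
cohort_band_matrix <- function(plants, tissues = sampled_tissues(),
                               combos = primer_combos(),
                               detection_fraction = 0.1) {
  if (is.null(names(plants))) names(plants) <- map_chr(plants, "id")
  per_plant <- if (is.list(tissues) && !is.null(names(tissues))) tissues else NULL
  long <- list_rbind(imap(plants, function(pl, nmp) {
    ts <- if (is.null(per_plant)) tissues else per_plant[[nmp]]
    list_rbind(map(ts, function(t) {
      transposon_display(pl, t, combos = combos,
                         detection_fraction = detection_fraction)
    })) |> mutate(plant = nmp)
  }))
  if (!nrow(long)) {
    return(tibble(plant = character(), locus_id = character(),
                  combo = character(), tissue = character(), present = logical()))
  }
  # complete: every locus x assayed tissue of every plant
  keys <- distinct(long, .data$locus_id, .data$combo)
  frames <- list_rbind(imap(plants, function(pl, nmp) {
    ts <- if (is.null(per_plant)) tissues else per_plant[[nmp]]
    tidyr::crossing(plant = nmp, keys, tissue = ts)
  }))
  frames |>
    left_join(long, by = c("plant", "locus_id", "combo", "tissue")) |>
    mutate(present = !is.na(.data$present)) |>
    select("plant", "locus_id", "combo", "tissue", "present")
}

#' Locus-specific SCAR PCR
#'
#' Amplifies across a known mPing insertion site and scores the filled
#' (element present) and empty (excised) alleles.
#'
#' @param plant A `plant`.
#' @param tissue A sampled tissue label.
#' @param locus_id An assayed marker locus (must have allele history in the
#'   tissue: baseline or a logged event).
#' @param detection_fraction Minimum cell fraction for an allele to be seen.
#' @return One of `"filled"`, `"empty"`, `"both"`.
#' @export
locus_pcr <- function(plant, tissue, locus_id, detection_fraction = 0.1) {
  if (!tissue %in% sampled_tissues()) abort(paste0("unknown tissue: ", tissue))
  base <- if (tissue == "E") plant$endosperm else plant$zygote
  hist_haps <- unique(c(
    base$hap[base$locus_id == locus_id],
    plant$events$hap[plant$events$locus_id == locus_id]
  ))
  if (!length(hist_haps)) abort(paste0("unknown locus: ", locus_id))
  geno <- tissue_genotype(plant, tissue)
  geno <- geno[geno$locus_id == locus_id & geno$fraction >= detection_fraction, ]
  filled <- unique(geno$hap)
  empty <- setdiff(c(1L, 2L), filled)
  if (!length(empty)) "filled" else if (!length(filled)) "empty" else "both"
}

#' In-silico CAPS digestion
#'
#' Cuts the amplicon at every occurrence of the recognition sequence,
#' `cut_offset` bases into the site (default `GTAC` cut as `GT^AC`, the
#' AfaI/RsaI site distinguishing C-type from T-type Ping).
#'
#' @param amplicon Nucleotide string (or `Biostrings::DNAString`).
#' @param recognition Recognition sequence.
#' @param cut_offset Cut position within the recognition site
#'   (0..nchar(recognition)).
#' @return Integer vector of ordered fragment lengths (summing to the
#'   amplicon length), with the fragment sequences as attribute
#'   `"fragments"`.
#' @export
caps_digest <- function(amplicon, recognition = "GTAC", cut_offset = 2) {
  amplicon <- as.character(amplicon)
  if (!nzchar(amplicon)) abort("empty amplicon")
  if (!nzchar(recognition)) abort("recognition sequence must be non-empty")
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    abort("cut_offset must lie within the recognition sequence")
  }
  hits <- Biostrings::matchPattern(recognition, Biostrings::DNAString(amplicon))
  cuts <- sort(unique(BiocGenerics::start(hits) - 1L + as.integer(cut_offset)))
  cuts <- cuts[cuts > 0 & cuts < nchar(amplicon)]
  bounds <- c(0L, cuts, nchar(amplicon))
  lens <- diff(bounds)
  frags <- substring(amplicon, head(bounds, -1) + 1, tail(bounds, -1))
  structure(as.integer(lens), fragments = frags)
}

#' Call the Ping SNP type from a CAPS fragment pattern
#'
#' The T-type amplicon lacks the site and stays full length; the C-type
#' amplicon is cut into two fragments; a heterozygote shows the union of
#' both patterns (three bands).
#'
#' @param fragments Integer vector of fragment lengths from [caps_digest()]
#'   on one or both allelic amplicons.
#' @return `"C-type"`, `"T-type"` or `"heterozygous"`.
#' @export
caps_call <- function(fragments) {
  lens <- sort(unique(as.integer(fragments)), decreasing = TRUE)
  if (length(lens) == 1) return("T-type")
  if (length(lens) == 2) return("C-type")
  if (length(lens) == 3 && lens[1] == sum(lens[-1])) return("heterozygous")
  abort("fragment pattern matches neither an uncut nor a single-cut amplicon")
}

check_ct <- function(ct) {
  need <- c("sample", "target_ct", "ref_ct", "is_calibrator")
  miss <- setdiff(need, names(ct))
  if (length(miss)) abort(paste0("CT table lacks column: ", miss[1]))
  if (sum(ct$is_calibrator) != 1) abort("exactly one calibrator sample is required")
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$ref_ct))) {
    abort("missing CT value")
  }
  if (any(ct$target_ct <= 0) || any(ct$ref_ct <= 0)) abort("CT values must be positive")
  invisible(ct)
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes the target CT to the reference gene (the UBQ5 role) within
#' each sample and to the calibrator sample across samples, assuming an
#' amplification efficiency of 2.
#'
#' @param ct Tibble with columns `sample`, `target_ct`, `ref_ct`,
#'   `is_calibrator` (exactly one `TRUE`).
#' @param sample Optional sample name(s) to return; default all.
#' @return Tibble `sample`, `delta_ct`, `ddct`, `rq` (relative quantity;
#'   1 at the calibrator).
#' @export
ddct <- function(ct, sample = NULL) {
  ct <- as_tibble(ct)
  check_ct(ct)
  cal <- ct[ct$is_calibrator, ]
  out <- ct |>
    mutate(delta_ct = .data$target_ct - .data$ref_ct,
           ddct = .data$delta_ct - (cal$target_ct - cal$ref_ct),
           rq = 2^(-.data$ddct)) |>
    select("sample", "delta_ct", "ddct", "rq")
  if (!is.null(sample)) out <- out[out$sample %in% sample, ]
  out
}

#' Copy number from qPCR
#'
#' Scales the calibrator's known copy count by the relative quantity of the
#' element target versus a single-copy reference.
#'
#' @param ct CT table as for [ddct()]; the calibrator is the strain with
#'   known copy number.
#' @param calibrator_copies Known copy count of the calibrator (> 0).
#' @param round_to_integer Round the estimates to whole copies.
#' @return Tibble `sample`, `copies`.
#' @export
copy_number_qpcr <- function(ct, calibrator_copies, round_to_integer = FALSE) {
  if (calibrator_copies <= 0) abort("calibrator_copies must be positive")
  out <- ddct(ct) |>
    mutate(copies = calibrator_copies * .data$rq) |>
    select("sample", "copies")
  if (round_to_integer) out$copies <- round(out$copies)
  out
}

#' Simulate a CT table from true expression or copy-number ratios
#'
#' Forward model for the qPCR assays: given true relative quantities (ratio
#' to the calibrator), produces target/reference CT values that [ddct()] or
#' [copy_number_qpcr()] invert exactly when `sd_noise = 0`.
#'
#' @param true_rq Named numeric vector of true relative quantities
#'   (calibrator must equal 1 and be named).
#' @param calibrator Name of the calibrator sample.
#' @param ref_ct Reference-gene CT common to all samples.
#' @param target_ct_cal Target CT of the calibrator.
#' @param sd_noise Gaussian CT noise (cycles) added to each well.
#' @param seed Seed used when `sd_noise > 0`.
#' @return A CT tibble suitable for [ddct()].
#' @export
simulate_ct_table <- function(true_rq, calibrator, ref_ct = 18,
                              target_ct_cal = 24, sd_noise = 0, seed = NULL) {
  stopifnot(calibrator %in% names(true_rq))
  if (sd_noise > 0) {
    if (is.null(seed)) abort("seed is required when sd_noise > 0")
    set.seed(as.integer(seed))
  }
  n <- length(true_rq)
  tct <- target_ct_cal - log2(true_rq / true_rq[[calibrator]])
  noise <- if (sd_noise > 0) stats::rnorm(n, 0, sd_noise) else 0
  tibble(
    sample = names(true_rq),
    target_ct = as.numeric(tct + noise),
    ref_ct = ref_ct,
    is_calibrator = names(true_rq) == calibrator
  )
}

#' Synthetic CAPS amplicons for the Ping +1261 SNP assay
#'
#' Deterministically constructs the 502-nt amplicon pair used as a worked
#' example of the CAPS assay: the C-type allele contains a single `GTAC`
#' (AfaI/RsaI) site placed so that the `GT^AC` cut releases fragments of
#' 352 and 150 bp; the T-type allele is identical except that the site is
#' ablated, so it stays full length. These are synthetic sequences (not the
#' published Ping amplicon); only the site geometry matches the assay. The
#' same pair is shipped as
#' `system.file("extdata", "caps_amplicons_synthetic.fasta",
#' package = "mpingr")`.
#'
#' @param length Amplicon length (nt).
#' @param cut_at Length of the 5' fragment released by the cut.
#' @return Named character vector with elements `C_type` and `T_type`.
#' @export
synthetic_caps_amplicons <- function(length = 502, cut_at = 352) {
  stopifnot(cut_at > 2, cut_at < length - 1)
  set.seed(1261)
  repeat {
    seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
    # plant the unique site so the cut (offset 2) falls at `cut_at`
    c_type <- paste0(substr(seq, 1, cut_at - 2), "GTAC",
                     substr(seq, cut_at + 3, length))
    t_type <- paste0(substr(seq, 1, cut_at - 2), "GTAT",
                     substr(seq, cut_at + 3, length))
    n_c <- Biostrings::countPattern("GTAC", Biostrings::DNAString(c_type))
    n_t <- Biostrings::countPattern("GTAC", Biostrings::DNAString(t_type))
    if (n_c == 1 && n_t == 0) break
  }
  c(C_type = c_type, T_type = t_type)
}
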