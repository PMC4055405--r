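# Strain models: Ping complement (copy number and the +1261 C/T intronic
# SNP type), baseline mPing insertion sets, and a developmental Ping
# expression profile for each ORF. The expression profile gates the
# transposition rate: mPing moves only while min(ORF1, ORF2) transcript
# level exceeds a threshold, which is how the early-embryogenesis peak of
# C-type Ping strains translates into the 3-5 DAP transposition burst while
# single-copy T-type strains stay inert.

#' Genome space for new insertions
#'
#' @param n_chrom Number of chromosomes (rice: 12).
#' @param chrom_len Chromosome length in bp (uniform; configurable).
#' @return A list with `chroms` (names) and `chrom_len`.
#' @export
genome_space <- function(n_chrom = 12, chrom_len = 3e7) {
  list(chroms = sprintf("chr%02d", seq_len(n_chrom)), chrom_len = chrom_len)
}

#' Developmental expression profile of a C-type Ping strain
#'
#' Piecewise-linear relative transcript level (Nipponbare ovary at
#' pollination = 1) for both ORFs, with a unique maximum at 3 DAP — the
#' early-embryogenesis burst characteristic of C-type Ping strains. Values
#' outside the anchor range are clamped to the boundary level.
#'
#' @param peak Relative level at the 3 DAP peak.
#' @return A tibble with columns `dap`, `orf1`, `orf2`.
#' @export
expression_profile_c_type <- function(peak = 8) {
  lv <- c(0.5, 0.5, 2, 5, peak, 4, 2, 0.7, 0.5)
  tibble(dap = c(-10, 0, 1, 2, 3, 4, 5, 6, 20), orf1 = lv, orf2 = lv)
}

#' Developmental expression profile of a T-type (or no-burst) Ping strain
#'
#' Basal expression with a shallow dip during early embryogenesis and no
#' interior peak; it never exceeds the default transposition threshold.
#'
#' @param level Basal relative level.
#' @return A tibble with columns `dap`, `orf1`, `orf2`.
#' @export
expression_profile_t_type <- function(level = 1) {
  lv <- level * c(1, 1, 0.8, 0.5, 0.4, 0.5, 0.8, 1, 1)
  tibble(dap = c(-10, 0, 1, 2, 3, 4, 5, 6, 20), orf1 = lv, orf2 = lv)
}

#' Interpolate an expression profile
#'
#' @param profile Tibble `dap`, `orf1`, `orf2`.
#' @param dap Times (DAP) to evaluate at.
#' @param orf `"orf1"`, `"orf2"` or `"min"` (the co-requirement of the
#'   Myb-like protein and the transposase).
#' @return Numeric vector of relative levels (clamped outside the anchors).
#' @export
expression_at <- function(profile, dap, orf = c("min", "orf1", "orf2")) {
  orf <- match.arg(orf)
  o1 <- approx(profile$dap, profile$orf1, xout = dap, rule = 2)$y
  if (orf == "orf1") return(o1)
  o2 <- approx(profile$dap, profile$orf2, xout = dap, rule = 2)$y
  if (orf == "orf2") return(o2)
  pmin(o1, o2)
}

#' Define a strain
#'
#' @param name Strain label.
#' @param ping Tibble of Ping copies with columns `locus` and `snp_type`
#'   (`"C"` or `"T"`); may have zero rows (no-Ping strains).
#' @param expression Expression profile tibble (`dap`, `orf1`, `orf2`);
#'   levels must be non-negative.
#' @param n_mping Number of baseline mPing loci to draw.
#' @param genome Genome space for locus coordinates.
#' @param seed Seed used to draw the baseline loci (makes strains pure
#'   functions of their arguments).
#' @return An object of class `strain_model`.
#' @export
strain_model <- function(name, ping, expression, n_mping, genome = genome_space(),
                         seed = 1) {
  stopifnot(is.data.frame(ping), all(c("locus", "snp_type") %in% names(ping)))
  if (nrow(ping) && !all(ping$snp_type %in% c("C", "T"))) {
    abort("ping snp_type must be 'C' or 'T'")
  }
  if (any(expression$orf1 < 0) || any(expression$orf2 < 0)) {
    abort("expression levels must be non-negative")
  }
  loci <- draw_loci(n_mping, genome, seed = seed, used = character())
  structure(
    list(name = name, ping = as_tibble(ping), expression = as_tibble(expression),
         mping_loci = loci, genome = genome),
    class = "strain_model"
  )
}

#' @export
print.strain_model <- function(x, ...) {
  cat("<strain_model> ", x$name, ": ", nrow(x$ping), " Ping (",
      paste(unique(x$ping$snp_type), collapse = "/"), "), ",
      nrow(x$mping_loci), " baseline mPing loci\n", sep = "")
  invisible(x)
}

# draw n fresh loci uniformly over the genome space, avoiding `used` ids;
# each locus carries the 2-bp flank read by the selective TD primers
draw_loci <- function(n, genome, seed = NULL, used = character()) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  locus_id = character(), flank = character()))
  }
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    k <- n - if (is.null(out)) 0 else nrow(out)
    chrom <- sample(genome$chroms, k, replace = TRUE)
    pos <- sample.int(genome$chrom_len, k, replace = TRUE) - 1L # 0-based
    cand <- tibble(
      chrom = chrom, pos = pos,
      locus_id = paste0(chrom, ":", pos),
      flank = random_flanks(k)
    )
    cand <- cand[!cand$locus_id %in% used & !duplicated(cand$locus_id), ]
    out <- bind_rows(out, cand)
    used <- c(used, cand$locus_id)
  }
  out[seq_len(n), ]
}

random_flanks <- function(n) {
  bases <- c("A", "C", "G", "T")
  paste0(sample(bases, n, replace = TRUE), sample(bases, n, replace = TRUE))
}

#' EG4-like strain (mPing-active)
#'
#' Seven C-type Ping copies, roughly one thousand baseline mPing loci, and
#' the early-embryogenesis expression burst.
#'
#' @param n_mping Baseline mPing copy number.
#' @param seed Seed for the baseline locus draw.
#' @param peak Expression peak level at 3 DAP.
#' @return A `strain_model`.
#' @export
strain_eg4 <- function(n_mping = 1000, seed = 101, peak = 8) {
  strain_model(
    "EG4",
    ping = tibble(locus = paste0("Ping-", 1:7), snp_type = "C"),
    expression = expression_profile_c_type(peak = peak),
    n_mping = n_mping, seed = seed
  )
}

#' Nipponbare-like strain (mPing-inactive)
#'
#' A single T-type Ping copy, ~50 baseline mPing loci, and sub-threshold
#' basal expression throughout development.
#'
#' @param n_mping Baseline mPing copy number.
#' @param seed Seed for the baseline locus draw.
#' @return A `strain_model`.
#' @export
strain_nipponbare <- function(n_mping = 50, seed = 102) {
  strain_model(
    "Nipponbare",
    ping = tibble(locus = "Ping-N", snp_type = "T"),
    expression = expression_profile_t_type(),
    n_mping = n_mping, seed = seed
  )
}

#' Default per-compartment rate multipliers
#'
#' Ping transcripts accumulate overwhelmingly in the embryo proper around
#' 3 DAP (much less in the endosperm and ovary wall), so the post-
#' regionalization embryo compartments (SAM, radicle progenitor, leaf
#' primordia) carry the full rate while the proembryo, the endosperm
#' lineage and the pre-fertilization gamete lineages are strongly reduced.
#' The SAM and radicle progenitor share the same multiplier (no default
#' asymmetry between shoot and radicle). All values are configurable.
#'
#' @return Named numeric vector of multipliers (compartments not listed
#'   default to 1).
#' @export
default_multipliers <- function() {
  c(proembryo = 0.03, endosperm = 0.01,
    egg = 0.002, sperm_to_egg = 0.002, sperm_to_central = 0.002,
    polar_nuclei = 0.002)
}

#' Transposition rate parameters
#'
#' The transposition rate in a compartment at time t is
#' `alpha * multiplier(compartment) * max(0, expression(t) - theta)` where
#' `expression` is the strain's min(ORF1, ORF2) relative level: transposition
#' requires Ping expression to exceed a threshold, so sub-threshold strains
#' are inert. Excisions occur at a fixed fraction of the insertion rate, and
#' an excised site is restored (from the sister chromatid or the homolog)
#' with probability `p_repair`.
#'
#' @param alpha Insertions per compartment-day per unit excess expression.
#'   `NULL` means "calibrate with [calibrate_alpha()] at simulation setup".
#' @param theta Expression threshold (relative units).
#' @param p_repair Probability an excision site is restored.
#' @param excision_fraction Excision rate as a fraction of the insertion rate.
#' @param multipliers Named numeric vector of per-compartment rate
#'   multipliers (default [default_multipliers()]; compartments not named
#'   get 1).
#' @param active_window Optional length-2 DAP interval outside of which the
#'   rate is forced to zero (used to confine events experimentally).
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(alpha = NULL, theta = 1, p_repair = 0.5,
                        excision_fraction = 0.1,
                        multipliers = default_multipliers(),
                        active_window = NULL) {
  if (!is.null(alpha) && alpha < 0) abort("alpha must be >= 0")
  if (p_repair < 0 || p_repair > 1) abort("p_repair must be in [0, 1]")
  if (excision_fraction < 0) abort("excision_fraction must be >= 0")
  structure(
    list(alpha = alpha, theta = theta, p_repair = p_repair,
         excision_fraction = excision_fraction,
         multipliers = multipliers, active_window = active_window),
    class = "rate_params"
  )
}

multiplier_for <- function(params, compartment) {
  m <- params$multipliers
  if (is.null(m)) return(1)
  if (compartment %in% names(m)) unname(m[[compartment]]) else 1
}

#' Instantaneous transposition rate
#'
#' @param strain A `strain_model`.
#' @param params A `rate_params` (with a non-`NULL` `alpha`).
#' @param compartment Compartment name (for its multiplier).
#' @param time Times (DAP); vectorized.
#' @return Non-negative numeric vector of insertion rates per
#'   compartment-day.
#' @export
transposition_rate <- function(strain, params, compartment, time) {
  alpha <- params$alpha
  if (is.null(alpha)) abort("alpha is NULL; calibrate it first (see calibrate_alpha)")
  excess <- pmax(0, expression_at(strain$expression, time) - params$theta)
  r <- alpha * multiplier_for(params, compartment) * excess
  if (!is.null(params$active_window)) {
    r[time < params$active_window[1] | time > params$active_window[2]] <- 0
  }
  r
}

# expected number of events visible in `tissue`, i.e. the integral of the
# insertion rate along the cell lineage path from the gamete lineages to the
# tissue's terminal compartment (trapezoid rule on a fine grid)
path_rate_integral <- function(strain, params, tree, tissue = "L2", dt = 0.01) {
  segs <- path_segments(tree, tissue)
  total <- 0
  for (i in seq_len(nrow(segs))) {
    if (segs$t_end[i] <= segs$t_start[i]) next
    grid <- seq(segs$t_start[i], segs$t_end[i], by = dt)
    if (length(grid) < 2) next
    r <- transposition_rate(strain, params, segs$compartment[i], grid)
    total <- total + sum((head(r, -1) + tail(r, -1)) / 2) * dt
  }
  total
}

# compartments (with time sub-intervals) whose events reach `tissue`
path_segments <- function(tree, tissue) {
  segs <- lineage_segments(tree)
  keep <- map_lgl(segs$tissues, function(ts) tissue %in% ts)
  segs <- segs[keep, c("compartment", "t_start", "t_end")]
  segs
}

#' Calibrate the rate constant to a target insertion load
#'
#' Chooses `alpha` so that the expected number of de novo insertions visible
#' in a reference sampled tissue equals `target` — the per-plant de novo
#' insertion load that the rate model is anchored to (default 15.5 per
#' plant, the load observed in selfed progenies of the active strain).
#'
#' @param strain A `strain_model`.
#' @param params A `rate_params`; its `alpha` is ignored.
#' @param tree A `lineage_tree`.
#' @param target Expected visible insertions per plant.
#' @param tissue Reference sampled tissue.
#' @return A `rate_params` with `alpha` set.
#' @export
calibrate_alpha <- function(strain, params = rate_params(), tree = default_lineage(),
                            target = 15.5, tissue = "L2") {
  unit <- params
  unit$alpha <- 1
  base <- path_rate_integral(strain, unit, tree, tissue = tissue)
  if (base <= 0) abort("expression never exceeds theta; cannot calibrate alpha")
  params$alpha <- target / base
  params
}
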