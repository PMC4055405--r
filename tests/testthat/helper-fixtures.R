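# Shared fixtures and independent oracles.

# small active strain for fast simulations
tiny_eg4 <- function(n_mping = 20, seed = 11) strain_eg4(n_mping = n_mping, seed = seed)

# parameters confining all activity to the SAM and radicle progenitor
# within 3-5 DAP (other compartments silenced via multipliers)
confined_params <- function(alpha = 1, excision_fraction = 0) {
  comps <- c("egg", "sperm_to_egg", "sperm_to_central", "polar_nuclei",
             "proembryo", "endosperm", "L1", "L2", "L3", "L4", "L5", "germline")
  rate_params(
    alpha = alpha,
    excision_fraction = excision_fraction,
    multipliers = c(setNames(rep(0, length(comps)), comps),
                    SAM = 1, radicle_progenitor = 1),
    active_window = c(3, 5)
  )
}

founder_plant <- function(strain, params, seed, ...) {
  f <- founder_genotypes(strain)
  simulate_plant(f$zygote, f$endosperm, strain, params, seed = seed, ...)
}

# a plant with a fixed genotype and no stochastic events, for genetics tests
manual_plant <- function(loci_hap1 = character(), loci_hap2 = character(),
                         strain = tiny_eg4(n_mping = 0), seed = 1,
                         forced_events = NULL, params = NULL) {
  mk <- function(ids, hap) {
    if (!length(ids)) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            locus_id = character(), hap = integer(),
                            flank = character()))
    }
    tibble::tibble(chrom = "chr01", pos = seq_along(ids) * 100L,
                   locus_id = ids, hap = as.integer(hap), flank = "AG")
  }
  ids <- union(loci_hap1, loci_hap2)
  base <- dplyr::bind_rows(
    mk(loci_hap1, 1) |> dplyr::mutate(pos = match(locus_id, ids) * 100L),
    mk(loci_hap2, 2) |> dplyr::mutate(pos = match(locus_id, ids) * 100L)
  )
  simulate_plant(base, base, strain,
                 params = params %||% rate_params(alpha = 0),
                 seed = seed, forced_events = forced_events, rate = FALSE)
}

# ---- independent lineage oracle ------------------------------------------
# literal transcription of the default ontogeny topology, used to
# cross-check tissues_containing/candidate_windows without touching the
# package's tree representation
oracle_children <- list(
  egg = list(c("proembryo", 0)),
  sperm_to_egg = list(c("proembryo", 0)),
  sperm_to_central = list(c("endosperm", 0)),
  polar_nuclei = list(c("endosperm", 0)),
  proembryo = list(c("SAM", 3), c("radicle_progenitor", 3)),
  SAM = list(c("L1", 5), c("L2", 6.5), c("L3", 8), c("L4", 12), c("L5", 15),
             c("germline", 60)),
  endosperm = list(), radicle_progenitor = list(),
  L1 = list(), L2 = list(), L3 = list(), L4 = list(), L5 = list(),
  germline = list()
)
oracle_tissue <- c(endosperm = "E", radicle_progenitor = "R",
                   L1 = "L1", L2 = "L2", L3 = "L3", L4 = "L4", L5 = "L5",
                   germline = "GERM")
oracle_birth <- c(egg = -10, sperm_to_egg = -10, sperm_to_central = -10,
                  polar_nuclei = -10, proembryo = 0, endosperm = 0, SAM = 3,
                  radicle_progenitor = 3, L1 = 5, L2 = 6.5, L3 = 8, L4 = 12,
                  L5 = 15, germline = 60)
oracle_end <- c(egg = 0, sperm_to_egg = 0, sperm_to_central = 0,
                polar_nuclei = 0, proembryo = 3, endosperm = 20, SAM = 60,
                radicle_progenitor = 20, L1 = 20, L2 = 20, L3 = 20, L4 = 20,
                L5 = 20, germline = 70)

oracle_reach <- function(comp, t) {
  out <- if (comp %in% names(oracle_tissue)) oracle_tissue[[comp]] else character()
  for (ch in oracle_children[[comp]]) {
    if (as.numeric(ch[2]) >= t) {
      out <- c(out, oracle_reach(ch[1], as.numeric(ch[2])))
    }
  }
  unique(out)
}

# all placements on a time grid, with their sampled-tissue footprints
oracle_grid <- function(step = 0.1) {
  out <- list()
  for (comp in names(oracle_children)) {
    ts <- seq(oracle_birth[[comp]], oracle_end[[comp]], by = step)
    for (t in ts) {
      out[[length(out) + 1]] <- list(
        compartment = comp, time = t,
        sampled = sort(intersect(oracle_reach(comp, t), sampled_tissues()))
      )
    }
  }
  out
}

# ---- independent classifier oracle ---------------------------------------
# direct per-rule lookup over a presence vector, written from the category
# definitions without reusing classify_insertion's control flow
oracle_classify <- function(present) {
  has <- function(x) x %in% present
  n_early <- sum(c("L1", "L2", "L3") %in% present)
  n_late <- sum(c("L4", "L5") %in% present)
  if (has("E")) {
    if (length(present) == 1) return("endosperm") else return("composite")
  }
  if (has("R") && (n_early + n_late) >= 1) return("radicle_shoot")
  if (has("R")) return("radicle")
  if (n_early >= 1 && n_late >= 1) return("shoot")
  if (n_early == 1 && n_late == 0) return("leaf")
  "uncategorized"
}
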