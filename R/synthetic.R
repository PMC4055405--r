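# Seeded generators for the three study designs: a selfed ontogeny cohort
# (S0 -> 8 S1 sampled at endosperm/radicle/leaf blades 1-5 -> 12 S2), two
# reciprocal F1 cohorts of 16 plants, and a 93-strain landrace panel split
# into no-Ping / C-type / T-type groups. Every generator is a pure function
# of its configuration and seed, and retains ground-truth event logs so
# classifier recovery can be measured exactly.

spawn_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a selfed ontogeny cohort
#'
#' Simulates a single parental plant (S0, sampled at its 2nd leaf blade),
#' `n_s1` selfed progenies sampled at endosperm, radicle and leaf blades
#' 1-5, and `n_s2` selfed progenies of the first S1 plant (sampled at the
#' 2nd leaf blade) for inheritance scoring. Band matrices cover all 16
#' selective primer combinations.
#'
#' @param strain A `strain_model` (default the active EG4-like strain).
#' @param params A `rate_params`; `alpha = NULL` is calibrated to the
#'   default 15.5 visible insertions per plant.
#' @param tree A `lineage_tree`.
#' @param n_s1,n_s2 Cohort sizes.
#' @param seed Integer seed (mandatory).
#' @param detection_fraction Band detection limit for TD.
#' @return A list of class `ontogeny_cohort` with elements `s0`, `s1`,
#'   `s2` (plants), `bands_s0`, `bands_s1`, `bands_s2` (long band
#'   matrices), `pedigree` (S2 -> S1 links), and `events` (ground-truth
#'   event log with plant ids).
#' @export
generate_ontogeny_cohort <- function(strain = strain_eg4(), params = rate_params(),
                                     tree = default_lineage(), n_s1 = 8,
                                     n_s2 = 12, seed = NULL,
                                     detection_fraction = 0.1) {
  if (is.null(seed)) abort("seed is mandatory")
  stopifnot(n_s1 >= 1, n_s2 >= 0)
  if (is.null(params$alpha)) params <- calibrate_alpha(strain, params, tree)
  seeds <- spawn_seeds(seed, 2 * (1 + n_s1 + n_s2) + 5)
  si <- 0; nxt <- function() { si <<- si + 1; seeds[si] }

  founder <- founder_genotypes(strain)
  s0 <- simulate_plant(founder$zygote, founder$endosperm, strain, params, tree,
                       seed = nxt(), id = "S0")
  s1 <- map(seq_len(n_s1), function(i) {
    g <- cross_plants(s0, s0, seed = nxt())
    simulate_plant(g$zygote, g$endosperm, strain, params, tree, seed = nxt(),
                   id = paste0("S1-", i),
                   pedigree = list(mother = "S0", father = "S0"))
  })
  names(s1) <- map_chr(s1, "id")
  s2_parent <- s1[[1]]
  s2 <- map(seq_len(n_s2), function(i) {
    g <- cross_plants(s2_parent, s2_parent, seed = nxt())
    simulate_plant(g$zygote, g$endosperm, strain, params, tree, seed = nxt(),
                   id = paste0("S2-", i),
                   pedigree = list(mother = s2_parent$id, father = s2_parent$id))
  })
  names(s2) <- map_chr(s2, "id")

  bands_s0 <- cohort_band_matrix(list(S0 = s0), tissues = "L2",
                                 detection_fraction = detection_fraction)
  bands_s1 <- cohort_band_matrix(s1, tissues = sampled_tissues(),
                                 detection_fraction = detection_fraction)
  bands_s2 <- if (n_s2 > 0) {
    cohort_band_matrix(s2, tissues = "L2",
                       detection_fraction = detection_fraction)
  } else {
    bands_s0[0, ]
  }
  pedigree <- tibble(plant = names(s2), parent = s2_parent$id)
  events <- list_rbind(imap(c(list(S0 = s0), s1, s2), function(pl, nmp) {
    if (!nrow(pl$events)) return(NULL)
    mutate(pl$events, plant = nmp)
  }))
  structure(
    list(s0 = s0, s1 = s1, s2 = s2, bands_s0 = bands_s0, bands_s1 = bands_s1,
         bands_s2 = bands_s2, pedigree = pedigree, events = events,
         strain = strain, params = params, tree = tree, seed = seed),
    class = "ontogeny_cohort"
  )
}

#' @export
print.ontogeny_cohort <- function(x, ...) {
  cat("<ontogeny_cohort> S0 + ", length(x$s1), " S1 + ", length(x$s2),
      " S2 plants (", x$strain$name, "-like), ",
      if (is.null(x$events)) 0L else nrow(x$events), " true events\n", sep = "")
  invisible(x)
}

#' Generate reciprocal F1 cohorts
#'
#' Crosses two strains in both directions (maternal listed first) and
#' simulates `n` F1 plants per direction, each sampled at the 2nd leaf
#' blade, together with the genotyped maternal-line parent matrices.
#'
#' @param strain_a,strain_b `strain_model`s (defaults: active EG4-like and
#'   inactive Nipponbare-like).
#' @param params_a,params_b Rate parameters per strain; `NULL` `alpha`
#'   values are calibrated per strain when possible, and fall back to the
#'   other strain's calibration scale for inert strains.
#' @param tree A `lineage_tree`.
#' @param n Plants per direction.
#' @param seed Integer seed (mandatory).
#' @param detection_fraction Band detection limit.
#' @return List of class `reciprocal_f1` with per-direction plants, band
#'   matrices, parent bands and the ground-truth event log.
#' @export
generate_reciprocal_f1 <- function(strain_a = strain_eg4(),
                                   strain_b = strain_nipponbare(),
                                   params_a = rate_params(),
                                   params_b = NULL,
                                   tree = default_lineage(), n = 16,
                                   seed = NULL, detection_fraction = 0.1) {
  if (is.null(seed)) abort("seed is mandatory")
  if (is.null(params_a$alpha)) params_a <- calibrate_alpha(strain_a, params_a, tree)
  if (is.null(params_b)) {
    # an inert strain cannot be calibrated against a positive target; it
    # shares the activity scale of the active parent
    params_b <- params_a
  } else if (is.null(params_b$alpha)) {
    params_b <- calibrate_alpha(strain_b, params_b, tree)
  }
  seeds <- spawn_seeds(seed, 4 + 4 * n)
  si <- 0; nxt <- function() { si <<- si + 1; seeds[si] }

  fa <- founder_genotypes(strain_a)
  fb <- founder_genotypes(strain_b)
  pa <- simulate_plant(fa$zygote, fa$endosperm, strain_a, params_a, tree,
                       seed = nxt(), id = paste0("P-", strain_a$name))
  pb <- simulate_plant(fb$zygote, fb$endosperm, strain_b, params_b, tree,
                       seed = nxt(), id = paste0("P-", strain_b$name))

  # the F1 zygote carries the active parent's Ping complement in one dose;
  # its expression profile follows the dominant (C-type-bearing) parent
  f1_strain <- if (any(strain_a$ping$snp_type == "C")) strain_a else strain_b
  f1_params <- if (any(strain_a$ping$snp_type == "C")) params_a else params_b

  sim_dir <- function(mother, father, dir_label) {
    plants <- map(seq_len(n), function(i) {
      g <- cross_plants(mother, father, seed = nxt())
      simulate_plant(g$zygote, g$endosperm, f1_strain, f1_params, tree,
                     seed = nxt(), id = sprintf("%s-F1-%02d", dir_label, i),
                     pedigree = list(mother = mother$id, father = father$id))
    })
    names(plants) <- map_chr(plants, "id")
    plants
  }
  dir1 <- sim_dir(pa, pb, paste0(strain_a$name, "x", strain_b$name))
  dir2 <- sim_dir(pb, pa, paste0(strain_b$name, "x", strain_a$name))

  structure(
    list(
      parents = list(a = pa, b = pb),
      dir1 = dir1, dir2 = dir2,
      bands_parents = cohort_band_matrix(
        setNames(list(pa, pb), c(pa$id, pb$id)), tissues = "L2",
        detection_fraction = detection_fraction),
      bands_dir1 = cohort_band_matrix(dir1, tissues = "L2",
                                      detection_fraction = detection_fraction),
      bands_dir2 = cohort_band_matrix(dir2, tissues = "L2",
                                      detection_fraction = detection_fraction),
      directions = c(paste0(strain_a$name, "/", strain_b$name),
                     paste0(strain_b$name, "/", strain_a$name)),
      seed = seed
    ),
    class = "reciprocal_f1"
  )
}

#' @export
print.reciprocal_f1 <- function(x, ...) {
  cat("<reciprocal_f1> ", length(x$dir1), " + ", length(x$dir2),
      " F1 plants (", paste(x$directions, collapse = " and "), ")\n", sep = "")
  invisible(x)
}

#' Generate a landrace panel with Ping groups and mPing copy numbers
#'
#' Emulates a panel of Aikoku/Gimbozu-type landraces split by Ping SNP type.
#' mPing copy numbers are overdispersed counts (negative binomial) with
#' group-specific means ordered C-type > T-type ~ no-Ping; only this
#' ordering and the significance behaviour are emulated, since per-strain
#' panel values are not published. The known C-type strains A119 (6 Ping
#' copies) and A123 (10 copies) are included by name; T-type strains carry a
#' single Ping copy.
#'
#' @param n_c,n_t,n_none Group sizes (defaults total 93 with the 14 stated
#'   T-type strains).
#' @param mu_base Mean copy number of the no-Ping and T-type groups.
#' @param shift Additional mean copy number of the C-type group (0 gives a
#'   global null).
#' @param size_base,size_c Negative-binomial size (overdispersion) per
#'   group.
#' @param seed Integer seed (mandatory).
#' @return Tibble `strain`, `group`, `ping_snp`, `ping_copies`,
#'   `mping_copies`.
#' @export
generate_ag_panel <- function(n_c = 48, n_t = 14, n_none = 31,
                              mu_base = 50, shift = 250,
                              size_base = 8, size_c = 1.5, seed = NULL) {
  if (is.null(seed)) abort("seed is mandatory")
  stopifnot(n_c >= 1, n_t >= 1, n_none >= 1)
  set.seed(as.integer(seed))
  groups <- c(rep("C-type", n_c), rep("T-type", n_t), rep("no-Ping", n_none))
  strain <- sprintf("AG%03d", seq_along(groups))
  strain[1] <- "A119"; if (n_c >= 2) strain[2] <- "A123"
  ping_copies <- c(
    { pc <- sample(1:10, n_c, replace = TRUE); pc[1] <- 6L; if (n_c >= 2) pc[2] <- 10L; pc },
    rep(1L, n_t),
    rep(0L, n_none)
  )
  mu <- ifelse(groups == "C-type", mu_base + shift, mu_base)
  size <- ifelse(groups == "C-type", size_c, size_base)
  tibble(
    strain = strain,
    group = groups,
    ping_snp = dplyr::case_when(groups == "C-type" ~ "C",
                                groups == "T-type" ~ "T",
                                TRUE ~ NA_character_),
    ping_copies = as.integer(ping_copies),
    mping_copies = rnbinom(length(groups), mu = mu, size = size)
  )
}
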