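# Stochastic cut-and-paste simulator. Events are drawn from an inhomogeneous
# Poisson process per compartment-lineage, with intensity gated by the
# strain's Ping expression profile (see transposition_rate). Each insertion
# creates a new locus with a random 2-bp flank; each excision removes an
# occupied locus from one haplotype and is restored with probability
# p_repair (sister-chromatid / homolog repair), in which case the copy
# number is unchanged. Compartments inherit the parental insertion set at
# their split time; an event at exactly the split time is inherited.

#' Founder genotypes for a strain
#'
#' Homozygous diploid zygote and matching endosperm (maternal set doubled
#' implicitly; haplotype 1 is maternal, 2 paternal throughout).
#'
#' @param strain A `strain_model`.
#' @return A list with tibbles `zygote` and `endosperm`
#'   (`chrom`, `pos`, `locus_id`, `hap`, `flank`).
#' @export
founder_genotypes <- function(strain) {
  g1 <- mutate(strain$mping_loci, hap = 1L)
  g2 <- mutate(strain$mping_loci, hap = 2L)
  z <- select(bind_rows(g1, g2), "chrom", "pos", "locus_id", "hap", "flank")
  list(zygote = z, endosperm = z)
}

# which side of the double fertilization a compartment belongs to, and which
# haplotypes its pre-fertilization events act on
comp_scope <- function(tree, compartment) {
  reach <- reachable_tissues(tree, compartment,
                             comp_row(tree, compartment)$birth)
  side <- if (length(reach) && all(reach == "E")) "endosperm" else "zygote"
  cfg <- tree$config$compartments
  entry <- cfg[[match(compartment, map_chr(cfg, "name"))]]
  origin <- entry$gamete_origin %||% NA_character_
  haps <- switch(
    compartment,
    egg = 1L, polar_nuclei = 1L,
    sperm_to_egg = 2L, sperm_to_central = 2L,
    if (identical(origin, "maternal")) 1L
    else if (identical(origin, "paternal")) 2L
    else c(1L, 2L)
  )
  list(side = side, haps = haps)
}

# lineage history feeding a compartment: (ancestor, exit time) pairs, where
# an ancestor event reaches the compartment iff event time <= exit time
ancestor_exits <- function(tree, compartment) {
  res <- list(tibble(compartment = compartment, exit = Inf))
  frontier <- list(list(name = compartment, cap = Inf))
  cfg <- tree$config$compartments
  nm <- map_chr(cfg, "name")
  while (length(frontier)) {
    cur <- frontier[[1]]; frontier <- frontier[-1]
    entry <- cfg[[match(cur$name, nm)]]
    birth <- comp_row(tree, cur$name)$birth
    for (p in unlist(entry$parents %||% character())) {
      res[[length(res) + 1]] <- tibble(compartment = p, exit = birth)
      frontier[[length(frontier) + 1]] <- list(name = p, cap = birth)
    }
  }
  out <- list_rbind(res)
  out |> group_by(.data$compartment) |>
    summarise(exit = max(.data$exit), .groups = "drop")
}

# genotype of a compartment's lineage just before `time`: side baseline plus
# ancestral insertions minus unrepaired ancestral excisions
compartment_genotype_at <- function(tree, compartment, time, zygote, endosperm,
                                    events) {
  scope <- comp_scope(tree, compartment)
  base <- if (scope$side == "endosperm") endosperm else zygote
  anc <- ancestor_exits(tree, compartment)
  anc$exit[anc$compartment == compartment] <- time
  if (nrow(events)) {
    ev <- left_join(events, anc, by = "compartment")
    ev <- ev[!is.na(ev$exit) & ev$time <= ev$exit, ]
  } else {
    ev <- events
  }
  geno <- base
  if (nrow(ev)) {
    ins <- ev[ev$kind == "insertion", ]
    if (nrow(ins)) {
      geno <- bind_rows(geno, select(ins, "chrom", "pos", "locus_id", "hap", "flank"))
    }
    exc <- ev[ev$kind == "excision" & !ev$repaired, ]
    if (nrow(exc)) {
      geno <- anti_join(geno, exc, by = c("locus_id", "hap"))
    }
  }
  geno
}

empty_events <- function() {
  tibble(
    event_id = integer(), kind = character(), compartment = character(),
    time = double(), chrom = character(), pos = integer(),
    locus_id = character(), hap = integer(), flank = character(),
    repaired = logical(), fraction = double(), tissues = list()
  )
}

#' Simulate one plant through ontogeny
#'
#' Runs the cut-and-paste process over every compartment of the lineage
#' tree, from the pre-fertilization gamete lineages to the sampling horizon.
#' Insertion times are drawn from the expression-gated inhomogeneous Poisson
#' process (discretized at `dt` DAP); excisions run at
#' `excision_fraction` times the insertion rate and pick an occupied locus.
#' The returned plant stores its baselines and the event log; per-tissue
#' genotypes are derived on demand by [tissue_genotype()].
#'
#' @param zygote,endosperm Diploid genotype tibbles as from
#'   [founder_genotypes()] or [cross_plants()].
#' @param strain A `strain_model`.
#' @param params A `rate_params`; a `NULL` `alpha` is calibrated via
#'   [calibrate_alpha()].
#' @param tree A `lineage_tree`.
#' @param seed Integer seed (required; the simulation is a pure function of
#'   its inputs and this seed).
#' @param forced_events Optional tibble with columns `compartment`, `time`
#'   and optionally `kind` ("insertion"/"excision"): events injected at
#'   exact placements instead of (in addition to) none drawn from the rate;
#'   when supplied together with `rate = FALSE` no stochastic events are
#'   drawn.
#' @param rate Draw stochastic events from the rate model (default `TRUE`).
#' @param id Plant identifier.
#' @param pedigree Optional list with `mother`/`father` ids.
#' @param dt Time discretization for event-time sampling (DAP).
#' @return An object of class `plant`.
#' @export
simulate_plant <- function(zygote, endosperm, strain, params = NULL,
                           tree = default_lineage(), seed = NULL,
                           forced_events = NULL, rate = TRUE,
                           id = "plant", pedigree = NULL, dt = 0.02) {
  if (is.null(seed)) abort("seed is required for a reproducible simulation")
  params <- params %||% rate_params()
  if (is.null(params$alpha)) {
    params <- calibrate_alpha(strain, params, tree)
  }
  set.seed(as.integer(seed))

  draws <- list()
  if (rate) {
    for (cp in tree$nodes$name) {
      row <- comp_row(tree, cp)
      if (row$end <= row$birth) next
      grid <- seq(row$birth, row$end, by = dt)
      if (length(grid) < 2) next
      lam <- transposition_rate(strain, params, cp, grid)
      lam_total <- sum((head(lam, -1) + tail(lam, -1)) / 2) * dt
      if (lam_total <= 0) next
      for (kind in c("insertion", "excision")) {
        mu <- lam_total * if (kind == "insertion") 1 else params$excision_fraction
        if (mu <= 0) next
        n_ev <- rpois(1, mu)
        if (n_ev == 0) next
        times <- sample(grid, n_ev, replace = TRUE, prob = pmax(lam, 0) + 1e-12)
        draws[[length(draws) + 1]] <-
          tibble(compartment = cp, time = times, kind = kind)
      }
    }
  }
  if (!is.null(forced_events) && nrow(forced_events)) {
    fe <- as_tibble(forced_events)
    if (!"kind" %in% names(fe)) fe$kind <- "insertion"
    draws[[length(draws) + 1]] <- select(fe, "compartment", "time", "kind")
  }
  cand <- if (length(draws)) arrange(list_rbind(draws), .data$time) else NULL

  events <- empty_events()
  used <- unique(c(zygote$locus_id, endosperm$locus_id))
  if (!is.null(cand)) {
    for (i in seq_len(nrow(cand))) check_placement(tree, cand$compartment[i], cand$time[i])
    scopes <- map(setNames(unique(cand$compartment), unique(cand$compartment)),
                  function(cp) comp_scope(tree, cp))
    tiss_all <- map2(cand$compartment, cand$time,
                     function(cp, tt) tissues_containing(tree, cp, tt))

    ins_idx <- which(cand$kind == "insertion")
    ins <- NULL
    if (length(ins_idx)) {
      loc <- draw_loci(length(ins_idx), strain$genome, seed = NULL, used = used)
      used <- c(used, loc$locus_id)
      hap <- map_int(cand$compartment[ins_idx], function(cp) {
        h <- scopes[[cp]]$haps
        if (length(h) == 1) h else sample(h, 1)
      })
      ins <- tibble(
        kind = "insertion", compartment = cand$compartment[ins_idx],
        time = cand$time[ins_idx], chrom = loc$chrom, pos = loc$pos,
        locus_id = loc$locus_id, hap = hap, flank = loc$flank,
        repaired = NA, fraction = 1, tissues = tiss_all[ins_idx]
      )
    }

    exc_idx <- which(cand$kind == "excision")
    exc_rows <- list()
    for (i in exc_idx) {
      cp <- cand$compartment[i]
      tt <- cand$time[i]
      sofar <- bind_rows(ins, list_rbind(exc_rows))
      if (is.null(sofar)) sofar <- empty_events()
      occ <- compartment_genotype_at(tree, cp, tt, zygote, endosperm, sofar)
      occ <- occ[occ$hap %in% scopes[[cp]]$haps, ]
      if (!nrow(occ)) next
      j <- sample.int(nrow(occ), 1)
      exc_rows[[length(exc_rows) + 1]] <- tibble(
        kind = "excision", compartment = cp, time = tt,
        chrom = occ$chrom[j], pos = occ$pos[j], locus_id = occ$locus_id[j],
        hap = occ$hap[j], flank = occ$flank[j],
        repaired = runif(1) < params$p_repair, fraction = 1,
        tissues = tiss_all[i]
      )
    }
    events <- bind_rows(ins, list_rbind(exc_rows))
    if (is.null(events) || !nrow(events)) {
      events <- empty_events()
    } else {
      events <- arrange(events, .data$time)
      events$event_id <- seq_len(nrow(events))
      events <- select(events, names(empty_events()))
    }
  }

  structure(
    list(id = id, strain = strain, zygote = zygote, endosperm = endosperm,
         events = events, tree = tree, params = params,
         pedigree = pedigree %||% list(mother = NA, father = NA), seed = seed),
    class = "plant"
  )
}

#' @export
print.plant <- function(x, ...) {
  cat("<plant> ", x$id, " (", x$strain$name, "-like): ",
      nrow(x$zygote), " baseline locus-haplotypes, ",
      sum(x$events$kind == "insertion"), " insertions, ",
      sum(x$events$kind == "excision"), " excisions\n", sep = "")
  invisible(x)
}

#' Genotype of a sampled tissue (or the germline)
#'
#' Reconstructs the insertion set present in a tissue: the side baseline
#' (endosperm or embryo) plus every logged insertion whose lineage reaches
#' the tissue, minus unrepaired excisions that reach it.
#'
#' @param plant A `plant`.
#' @param tissue One of the sampled tissue labels or `"GERM"`.
#' @return Tibble `chrom`, `pos`, `locus_id`, `hap`, `flank`, `fraction`.
#' @export
tissue_genotype <- function(plant, tissue) {
  if (!tissue %in% all_tissue_labels()) {
    abort(paste0("unknown tissue: ", tissue))
  }
  base <- if (tissue == "E") plant$endosperm else plant$zygote
  geno <- mutate(base, fraction = 1)
  ev <- plant$events
  if (nrow(ev)) {
    reach <- map_lgl(ev$tissues, function(ts) tissue %in% ts)
    ins <- ev[reach & ev$kind == "insertion", ]
    if (nrow(ins)) {
      geno <- bind_rows(geno, select(ins, "chrom", "pos", "locus_id", "hap",
                                     "flank", "fraction"))
    }
    exc <- ev[reach & ev$kind == "excision" & !ev$repaired, ]
    if (nrow(exc)) geno <- anti_join(geno, exc, by = c("locus_id", "hap"))
  }
  geno
}

#' Draw gametes from a plant's germline
#'
#' Meiosis without linkage: every heterozygous germline insertion is
#' transmitted independently with probability 1/2; homozygous insertions are
#' always transmitted.
#'
#' @param plant A `plant` (its lineage tree must include a germline).
#' @param n Number of gametes (> 0).
#' @param seed Integer seed.
#' @return A `gamete_set`: list with `loci` (tibble, one row per germline
#'   locus with its zygosity) and `carry` (loci x n logical matrix). Use
#'   [gamete_genotype()] to materialize one haploid genome.
#' @export
make_gametes <- function(plant, n, seed = NULL) {
  if (n <= 0) abort("n must be > 0")
  if (is.null(seed)) abort("seed is required")
  set.seed(as.integer(seed))
  germ <- tissue_genotype(plant, "GERM")
  loci <- germ |> group_by(.data$chrom, .data$pos, .data$locus_id, .data$flank) |>
    summarise(zygosity = length(unique(.data$hap)), .groups = "drop") |>
    arrange(.data$chrom, .data$pos)
  carry <- matrix(TRUE, nrow = nrow(loci), ncol = n)
  het <- which(loci$zygosity == 1)
  if (length(het) && n > 0) {
    carry[het, ] <- matrix(runif(length(het) * n) < 0.5,
                           nrow = length(het), ncol = n)
  }
  structure(list(loci = loci, carry = carry, n = n), class = "gamete_set")
}

#' Materialize one gamete
#'
#' @param gametes A `gamete_set`.
#' @param i Gamete index.
#' @return Haploid genome tibble (`chrom`, `pos`, `locus_id`, `flank`).
#' @export
gamete_genotype <- function(gametes, i) {
  stopifnot(i >= 1, i <= gametes$n)
  select(gametes$loci[gametes$carry[, i], ], "chrom", "pos", "locus_id", "flank")
}

#' Cross two plants
#'
#' Double fertilization: one sperm fuses with the egg (zygote), the other —
#' a mitotic sister carrying the same generative-cell genotype — with the
#' central cell whose two polar nuclei are mitotic copies of the same
#' megaspore product as the egg. The zygote is egg + sperm; the endosperm is
#' the maternal set (doubled) + the same sperm set.
#'
#' @param maternal,paternal `plant` objects.
#' @param seed Integer seed.
#' @return List with `zygote` and `endosperm` genotype tibbles (haplotype 1
#'   maternal, 2 paternal), ready for [simulate_plant()].
#' @export
cross_plants <- function(maternal, paternal, seed = NULL) {
  if (is.null(seed)) abort("seed is required")
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max, 2)
  egg <- gamete_genotype(make_gametes(maternal, 1, seed = sub[1]), 1)
  sperm <- gamete_genotype(make_gametes(paternal, 1, seed = sub[2]), 1)
  zyg <- bind_rows(mutate(egg, hap = 1L), mutate(sperm, hap = 2L)) |>
    select("chrom", "pos", "locus_id", "hap", "flank")
  list(zygote = zyg, endosperm = zyg)
}
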