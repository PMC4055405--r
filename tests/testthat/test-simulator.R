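test_that("the rate law is threshold-gated with the closed form", {
  st <- tiny_eg4()
  # constant profile two units above threshold: rate = alpha * mult * 2
  st$expression <- tibble::tibble(dap = c(-10, 20), orf1 = 3, orf2 = 3)
  p <- rate_params(alpha = 1, theta = 1)
  expect_equal(transposition_rate(st, p, "SAM", 4), 2)
  p2 <- rate_params(alpha = 1.5, theta = 1, multipliers = c(SAM = 2))
  expect_equal(transposition_rate(st, p2, "SAM", 4), 1.5 * 2 * 2)
  # expression exactly at threshold gives zero
  st$expression <- tibble::tibble(dap = c(-10, 20), orf1 = 1, orf2 = 1)
  expect_equal(transposition_rate(st, p, "SAM", 4), 0)
  # the two ORFs are co-required: the lower one limits the rate
  st$expression <- tibble::tibble(dap = c(-10, 20), orf1 = 5, orf2 = 2)
  expect_equal(transposition_rate(st, p, "SAM", 4), 1)
})

test_that("a T-type strain never exceeds the threshold", {
  nip <- strain_nipponbare(n_mping = 10, seed = 2)
  p <- rate_params(alpha = 5, theta = 1)
  expect_true(all(transposition_rate(nip, p, "SAM", seq(-10, 20, by = 0.1)) == 0))
  pl <- founder_plant(nip, p, seed = 3)
  expect_equal(nrow(pl$events), 0)
})

test_that("alpha = 0 gives an empty event log and identical tissues", {
  pl <- founder_plant(tiny_eg4(), rate_params(alpha = 0), seed = 5)
  expect_equal(nrow(pl$events), 0)
  g_r <- tissue_genotype(pl, "R")
  g_l5 <- tissue_genotype(pl, "L5")
  expect_equal(dplyr::arrange(g_r, locus_id, hap),
               dplyr::arrange(g_l5, locus_id, hap))
})

test_that("identical seeds give identical event logs", {
  st <- tiny_eg4()
  p <- calibrate_alpha(st)
  a <- founder_plant(st, p, seed = 77)
  b <- founder_plant(st, p, seed = 77)
  expect_identical(a$events, b$events)
  c <- founder_plant(st, p, seed = 78)
  expect_false(identical(a$events, c$events))
})

test_that("simulation requires a seed", {
  st <- tiny_eg4()
  f <- founder_genotypes(st)
  expect_error(simulate_plant(f$zygote, f$endosperm, st, rate_params(alpha = 0)),
               "seed")
})

test_that("per-cell copy number changes by +1, 0 or -1 per event", {
  st <- tiny_eg4(n_mping = 50)
  p <- calibrate_alpha(st, rate_params(p_repair = 0.5, excision_fraction = 0.5))
  pl <- founder_plant(st, p, seed = 9)
  ev <- pl$events
  expect_true(nrow(ev) > 0)
  for (tis in c("L2", "R", "GERM", "E")) {
    base_n <- nrow(if (tis == "E") pl$endosperm else pl$zygote)
    reach <- vapply(ev$tissues, function(ts) tis %in% ts, TRUE)
    delta <- sum(reach & ev$kind == "insertion") -
      sum(reach & ev$kind == "excision" & !ev$repaired)
    expect_equal(nrow(tissue_genotype(pl, tis)), base_n + delta)
  }
})

test_that("guaranteed repair keeps an excised locus in all descendants", {
  pl <- manual_plant(
    loci_hap1 = "chr01:100", loci_hap2 = "chr01:100",
    params = rate_params(alpha = 0, p_repair = 1),
    forced_events = tibble::tibble(compartment = "proembryo", time = 1,
                                   kind = "excision")
  )
  expect_equal(pl$events$kind, "excision")
  expect_true(pl$events$repaired)
  for (tis in c("R", "L1", "L5", "GERM")) {
    expect_equal(nrow(tissue_genotype(pl, tis)), 2)
  }
})

test_that("an unrepaired excision empties the locus in descendant tissues only", {
  pl <- manual_plant(
    loci_hap1 = "chr01:100", loci_hap2 = "chr01:100",
    params = rate_params(alpha = 0, p_repair = 0),
    forced_events = tibble::tibble(compartment = "radicle_progenitor",
                                   time = 4, kind = "excision")
  )
  expect_false(pl$events$repaired)
  expect_equal(nrow(tissue_genotype(pl, "R")), 1)   # one haplotype lost
  expect_equal(nrow(tissue_genotype(pl, "L1")), 2)  # shoot unaffected
  expect_equal(locus_pcr(pl, "R", "chr01:100"), "both")
  expect_equal(locus_pcr(pl, "L1", "chr01:100"), "filled")
})

test_that("pre-fertilization events split embryo from endosperm correctly", {
  # egg-lineage event: embryo yes, endosperm no (post egg/polar divergence)
  pl_egg <- manual_plant(
    forced_events = tibble::tibble(compartment = "egg", time = -5)
  )
  ev <- pl_egg$events
  expect_equal(ev$hap, 1L) # maternal haplotype
  expect_true(all(c("R", "L1", "GERM") %in% ev$tissues[[1]]))
  expect_false("E" %in% ev$tissues[[1]])
  expect_equal(nrow(tissue_genotype(pl_egg, "E")), 0)
  expect_equal(nrow(tissue_genotype(pl_egg, "L3")), 1)

  # polar-nuclei event: endosperm only
  pl_pol <- manual_plant(
    forced_events = tibble::tibble(compartment = "polar_nuclei", time = -5)
  )
  expect_equal(pl_pol$events$tissues[[1]], "E")
  expect_equal(nrow(tissue_genotype(pl_pol, "E")), 1)
  expect_equal(nrow(tissue_genotype(pl_pol, "L1")), 0)
})

test_that("the realized event count matches the analytic Poisson mean", {
  st <- tiny_eg4(n_mping = 5)
  p <- calibrate_alpha(st, rate_params(excision_fraction = 0))
  # analytic expectation of germline-visible insertions: integral of the
  # rate along egg/sperm -> proembryo -> SAM -> germline, trapezoid rule
  path <- list(c("egg", -10, 0), c("sperm_to_egg", -10, 0),
               c("proembryo", 0, 3), c("SAM", 3, 60), c("germline", 60, 70))
  mu <- 0
  for (seg in path) {
    tt <- seq(as.numeric(seg[2]), as.numeric(seg[3]), by = 0.005)
    r <- transposition_rate(st, p, seg[1], tt)
    mu <- mu + sum((head(r, -1) + tail(r, -1)) / 2) * 0.005
  }
  n_rep <- 150
  counts <- vapply(seq_len(n_rep), function(i) {
    pl <- founder_plant(st, p, seed = 1000 + i)
    sum(pl$events$kind == "insertion" &
          vapply(pl$events$tissues, function(ts) "GERM" %in% ts, TRUE))
  }, numeric(1))
  se <- sqrt(mu / n_rep) # Poisson variance
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("meiosis transmits heterozygous loci at one half", {
  pl <- manual_plant(loci_hap1 = c("chr01:100", "chr01:200"),
                     loci_hap2 = "chr01:100")
  gs <- make_gametes(pl, 4000, seed = 21)
  hom <- which(gs$loci$locus_id == "chr01:100")
  het <- which(gs$loci$locus_id == "chr01:200")
  expect_true(all(gs$carry[hom, ]))
  frac <- mean(gs$carry[het, ])
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_error(make_gametes(pl, 0, seed = 1), "n must be")
})

test_that("a radicle-confined event is never transmitted", {
  pl <- manual_plant(
    forced_events = tibble::tibble(compartment = "radicle_progenitor", time = 4)
  )
  loc <- pl$events$locus_id
  gs <- make_gametes(pl, 200, seed = 3)
  expect_false(loc %in% gs$loci$locus_id)
})

test_that("selfing retains homozygous loci and the generative-cell rule holds", {
  pl <- manual_plant(loci_hap1 = c("chr01:100", "chr01:200"),
                     loci_hap2 = c("chr01:100"))
  g <- cross_plants(pl, pl, seed = 31)
  expect_true("chr01:100" %in% g$zygote$locus_id[g$zygote$hap == 1])
  expect_true("chr01:100" %in% g$zygote$locus_id[g$zygote$hap == 2])
  # both sperm are mitotic copies of one meiotic product: a paternal locus
  # is either in both fertilization products or in neither
  for (s in 1:25) {
    g2 <- cross_plants(pl, pl, seed = 100 + s)
    in_zyg <- "chr01:200" %in% g2$zygote$locus_id[g2$zygote$hap == 2]
    in_end <- "chr01:200" %in% g2$endosperm$locus_id[g2$endosperm$hap == 2]
    expect_equal(in_zyg, in_end)
  }
})

test_that("a heterozygous germline insertion reaches ~3/4 of selfed progeny", {
  pl <- manual_plant(loci_hap1 = "chr01:100")
  n <- 600
  hits <- vapply(seq_len(n), function(i) {
    g <- cross_plants(pl, pl, seed = 5000 + i)
    "chr01:100" %in% g$zygote$locus_id
  }, TRUE)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(mean(hits) - 0.75), 3 * se)
})
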