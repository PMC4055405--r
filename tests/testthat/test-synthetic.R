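small_eg4 <- function() strain_eg4(n_mping = 60, seed = 101)

test_that("generators demand a seed and are reproducible", {
  expect_error(generate_ontogeny_cohort(strain = small_eg4()), "seed")
  expect_error(generate_reciprocal_f1(), "seed")
  expect_error(generate_ag_panel(), "seed")
  a <- generate_ontogeny_cohort(strain = small_eg4(), n_s1 = 2, n_s2 = 2,
                                seed = 7)
  b <- generate_ontogeny_cohort(strain = small_eg4(), n_s1 = 2, n_s2 = 2,
                                seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$bands_s1, b$bands_s1)
  p1 <- generate_ag_panel(seed = 5)
  p2 <- generate_ag_panel(seed = 5)
  expect_identical(p1, p2)
})

test_that("a zero-rate strain yields no de novo bands anywhere", {
  coh <- generate_ontogeny_cohort(strain = small_eg4(),
                                  params = rate_params(alpha = 0),
                                  n_s1 = 3, n_s2 = 0, seed = 11)
  expect_equal(nrow(coh$events), 0)
  calls <- call_de_novo(coh$bands_s0, coh$bands_s1)
  expect_equal(sum(calls$status == "de_novo"), 0)
  expect_true(all(calls$status == "ancestral"))
})

test_that("every de novo band traces back to a logged ground-truth event", {
  coh <- generate_ontogeny_cohort(strain = small_eg4(), n_s1 = 4, n_s2 = 0,
                                  seed = 13)
  calls <- call_de_novo(coh$bands_s0, coh$bands_s1)
  dn <- calls[calls$status == "de_novo", ]
  expect_gt(nrow(dn), 0)
  truth <- paste(coh$events$plant, coh$events$locus_id)
  expect_true(all(paste(dn$plant, dn$locus_id) %in% truth))
})

test_that("the default cohort is dominated by shoot- and radicle-specific calls", {
  coh <- generate_ontogeny_cohort(strain = small_eg4(), seed = 2024, n_s2 = 0)
  calls <- classify_calls(call_de_novo(coh$bands_s0, coh$bands_s1),
                          tree = coh$tree)
  dn <- calls[calls$status == "de_novo", ]
  s <- summarize_cohort(dn, n_plants = length(coh$s1))
  expect_gt(category_share(s, c("shoot", "radicle"), percent = FALSE), 0.75)
  expect_gt(s$mean_per_plant, 10)
})

test_that("reciprocal F1 cohorts show activity in both directions", {
  f1 <- generate_reciprocal_f1(strain_a = small_eg4(), n = 4, seed = 17)
  counts <- function(bands, parents_bands) {
    calls <- call_de_novo(parents_bands, bands)
    sum(calls$status == "de_novo")
  }
  n1 <- counts(f1$bands_dir1, f1$bands_parents)
  n2 <- counts(f1$bands_dir2, f1$bands_parents)
  expect_gt(n1, 0)
  expect_gt(n2, 0)
  # bands private to the inactive parent line are attributed, not de novo
  calls <- call_de_novo(f1$bands_parents[f1$bands_parents$plant == "P-EG4", ],
                        f1$bands_dir1)
  expect_true(any(calls$status == "other_parent"))
})

test_that("both parents inert gives zero de novo in both directions", {
  nip_a <- strain_nipponbare(n_mping = 30, seed = 1)
  nip_b <- strain_nipponbare(n_mping = 30, seed = 2)
  f1 <- generate_reciprocal_f1(strain_a = nip_a, strain_b = nip_b,
                               params_a = rate_params(alpha = 1),
                               params_b = rate_params(alpha = 1),
                               n = 3, seed = 19)
  for (bands in list(f1$bands_dir1, f1$bands_dir2)) {
    calls <- call_de_novo(f1$bands_parents, bands)
    expect_equal(sum(calls$status == "de_novo"), 0)
  }
})

test_that("the landrace panel has the configured structure and ordering", {
  panel <- generate_ag_panel(seed = 23)
  expect_equal(nrow(panel), 93)
  expect_equal(sum(panel$group == "T-type"), 14)
  expect_equal(panel$ping_copies[panel$strain == "A119"], 6)
  expect_equal(panel$ping_copies[panel$strain == "A123"], 10)
  expect_true(all(panel$ping_copies[panel$group == "T-type"] == 1))
  expect_true(all(panel$ping_copies[panel$group == "no-Ping"] == 0))
  med <- tapply(panel$mping_copies, panel$group, median)
  expect_gt(med[["C-type"]], med[["T-type"]])
  expect_gt(med[["C-type"]], med[["no-Ping"]])

  tt <- tidy(steel_dwass(panel, mping_copies, group))
  c_pairs <- tt[tt$group1 == "C-type" | tt$group2 == "C-type", ]
  expect_true(all(c_pairs$p_value < 0.01))
})

test_that("a null panel shows no significant group differences at the nominal rate", {
  hits <- vapply(1:30, function(i) {
    panel <- generate_ag_panel(shift = 0, size_c = 8, seed = 400 + i)
    min(tidy(steel_dwass(panel, mping_copies, group))$p_value) < 0.01
  }, TRUE)
  expect_lt(mean(hits), 0.2)
})

test_that("shipped scenario configs parse and drive the generators", {
  sc <- read_scenario(system.file("extdata", "scenario_ag_panel.yaml",
                                  package = "mpingr"))
  expect_equal(sc$design, "ag_panel")
  panel <- generate_ag_panel(n_c = sc$n_c, n_t = sc$n_t, n_none = sc$n_none,
                             mu_base = sc$mu_base, shift = sc$shift,
                             size_base = sc$size_base, size_c = sc$size_c,
                             seed = 3)
  expect_equal(nrow(panel), sc$n_c + sc$n_t + sc$n_none)
  expect_error(read_scenario(system.file("extdata", "lineage_default.yaml",
                                         package = "mpingr")),
               "design")
})

test_that("summary plots return ggplot objects", {
  s <- summarize_cohort(calls_from_counts(c(shoot = 5, radicle = 3)))
  expect_s3_class(autoplot(s), "ggplot")
  panel <- generate_ag_panel(seed = 29)
  expect_s3_class(plot_copy_numbers(panel), "ggplot")
  expect_s3_class(plot_lineage(default_lineage()), "ggplot")
})
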