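# small long-format band matrix builder: bands[[plant]] is a character
# vector of tissues per locus, e.g. list(P1 = c(l1 = "L1,L4"))
band_fixture <- function(per_plant, tissues = sampled_tissues()) {
  rows <- list()
  for (pn in names(per_plant)) {
    spec <- per_plant[[pn]]
    loci <- names(spec)
    for (lc in loci) {
      pres <- strsplit(spec[[lc]], ",", fixed = TRUE)[[1]]
      pres <- pres[nzchar(pres)]
      rows[[length(rows) + 1]] <- tibble::tibble(
        plant = pn, locus_id = lc, combo = "AA", tissue = tissues,
        present = tissues %in% pres
      )
    }
  }
  proto <- tibble::tibble(plant = character(), locus_id = character(),
                          combo = character(), tissue = character(),
                          present = logical())
  dplyr::bind_rows(c(list(proto), rows))
}

test_that("de novo calling separates de novo, ancestral, other-parent and anomalous bands", {
  progeny <- band_fixture(list(
    P1 = c(anc = "L1", nip = "L1", dn = "L1,L4", anom = "L1"),
    P2 = c(anc = "L2", nip = "L2", dn = "", anom = "L3"),
    P3 = c(anc = "L1", nip = "L5", dn = "", anom = "")
  ))
  parent <- band_fixture(list(S0 = c(anc = "L2")))
  calls <- call_de_novo(parent, progeny)
  st <- setNames(calls$status, calls$locus_id)
  expect_equal(unname(st["anc"]), "ancestral")
  expect_equal(unname(st["nip"]), "other_parent")
  expect_equal(unname(st["dn"]), "de_novo")
  expect_equal(unname(st["anom"]), "anomalous")
  expect_equal(calls$plant[calls$locus_id == "dn"], "P1")
  expect_setequal(calls$present_tissues[calls$locus_id == "dn"][[1]],
                  c("L1", "L4"))
  expect_error(call_de_novo(dplyr::select(parent, -combo), progeny), "lacks")
})

test_that("classification follows the organ-specificity rules", {
  expect_equal(classify_insertion("L1"), "leaf")
  expect_equal(classify_insertion(c("L1", "L4")), "shoot")
  expect_equal(classify_insertion(c("R", "L2", "L5")), "radicle_shoot")
  expect_equal(classify_insertion("L4"), "uncategorized")
  expect_equal(classify_insertion("E"), "endosperm")
  expect_equal(classify_insertion("R"), "radicle")
  expect_equal(classify_insertion(c("R", "L1")), "radicle_shoot")
  expect_equal(classify_insertion(c("L1", "L2")), "uncategorized")
  expect_equal(classify_insertion(c("E", "R")), "composite")
  expect_error(classify_insertion(character()), "all-absent")
  expect_error(classify_insertion("X"), "unknown tissue")
})

test_that("classify_insertion agrees with the rule-table oracle on all patterns", {
  tissues <- sampled_tissues()
  for (mask in 1:(2^7 - 1)) {
    pres <- tissues[bitwAnd(mask, 2^(0:6)) > 0]
    expect_equal(classify_insertion(pres), oracle_classify(pres),
                 label = paste("pattern", paste(pres, collapse = "+")))
  }
})

test_that("timing inference delegates to the lineage inversion", {
  tree <- default_lineage()
  w <- infer_timing(c("L1", "L4"), tree)
  expect_equal(w$compartment, "SAM")
  expect_equal(c(w$t_start, w$t_end), c(3, 5))
  w2 <- infer_timing(c("R", "L1"), tree)
  expect_true("proembryo" %in% w2$compartment)
  expect_true(all(w2$t_end <= 3))
  w3 <- infer_timing("E", tree)
  expect_true(all(w3$compartment %in%
                    c("endosperm", "polar_nuclei", "sperm_to_central")))
})

test_that("classified calls carry category, first leaf, windows and heritability", {
  progeny <- band_fixture(list(
    P1 = c(a = "L1,L2,L3,L4,L5", b = "R", c = "L2"),
    P2 = c(a = "", b = "", c = "")
  ))
  parent <- band_fixture(list(S0 = c()))
  calls <- classify_calls(call_de_novo(parent, progeny))
  calls <- calls[order(calls$locus_id), ]
  expect_equal(calls$category, c("shoot", "radicle", "leaf"))
  expect_equal(calls$first_leaf, c("L1", NA, "L2"))
  expect_equal(calls$heritable_pred, c(TRUE, FALSE, FALSE))
  expect_match(calls$timing[1], "3–5 DAP SAM")
})

test_that("inheritance scoring matches prediction and the printed convention", {
  expect_equal(score_inheritance(11, 13)$percent, 85)
  expect_equal(round(score_inheritance(11, 13)$fraction, 3), 0.846)
  expect_error(score_inheritance(3, 0), "detected")

  s1 <- band_fixture(list(
    S1 = c(sh = "L1,L4", rd = "R", lf = "L2"),
    S1b = c(sh = "", rd = "", lf = "")
  ))
  parent <- band_fixture(list(S0 = c()))
  s1_calls <- classify_calls(call_de_novo(parent, s1))
  # shoot-specific band reappears in 2 of 3 S2 plants; the others never do
  s2 <- band_fixture(list(
    S2a = c(sh = "L2"), S2b = c(sh = "L2"), S2c = c(sh = "")
  ), tissues = "L2")
  ped <- tibble::tibble(plant = c("S2a", "S2b", "S2c"), parent = "S1")
  res <- predict_and_measure_inheritance(s1_calls, s2, ped)
  bc <- res$by_category
  expect_equal(bc$predicted_heritable[bc$category == "shoot"], TRUE)
  expect_equal(bc$predicted_heritable[bc$category == "radicle"], FALSE)
  expect_equal(bc$predicted_heritable[bc$category == "leaf"], FALSE)
  expect_equal(bc$inherited[bc$category == "shoot"], 1)
  expect_equal(bc$inherited[bc$category == "radicle"], 0)
  expect_equal(bc$percent[bc$category == "shoot"], 100)
  expect_equal(bc$p_detect_mendelian[1], 1 - (1 / 4)^3)
  expect_error(predict_and_measure_inheritance(s1_calls, s2,
                                               tibble::tibble(plant = "x")),
               "lacks")
})

test_that("excision classification reuses the insertion rules", {
  st <- c(E = "filled", R = "empty", L1 = "filled", L2 = "filled",
          L3 = "filled", L4 = "filled", L5 = "filled")
  expect_equal(classify_excision(st), "radicle")
  st2 <- st; st2[["R"]] <- "filled"; st2[["L1"]] <- "both"; st2[["L4"]] <- "empty"
  expect_equal(classify_excision(st2), "shoot")
  expect_equal(classify_excision(setNames(rep("filled", 7), sampled_tissues())),
               "no_excision")
  expect_error(classify_excision(c(E = "filled", X = "empty")), "unknown tissue")
  expect_error(classify_excision(c(E = "weird")), "filled/empty/both")
})

test_that("survey_excisions recovers a forced radicle excision", {
  pl <- manual_plant(
    loci_hap1 = c("chr01:100", "chr01:200"),
    loci_hap2 = c("chr01:100", "chr01:200"),
    params = rate_params(alpha = 0, p_repair = 0),
    forced_events = tibble::tibble(compartment = "radicle_progenitor",
                                   time = 4, kind = "excision")
  )
  sv <- survey_excisions(pl)
  excised <- sv[sv$category != "no_excision", ]
  expect_equal(nrow(excised), 1)
  expect_equal(excised$category, "radicle")
  expect_equal(excised$R, "both")
  expect_equal(excised$L1, "filled")
})
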