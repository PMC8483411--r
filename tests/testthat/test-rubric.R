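# Binding calls, rubric point schedules, bonuses and final aggregation.

P1 <- challenge_rubric(1)
P2 <- challenge_rubric(2)

test_that("call_binding thresholds behave exactly at the boundaries", {
  expect_true(call_binding(5000, FALSE, P1)$binds_as_pro)
  expect_true(call_binding(10000, FALSE, P1)$binds_as_pro)   # 10 uM binds
  expect_false(call_binding(10001, FALSE, P1)$binds_as_pro)
  expect_false(call_binding(30000, FALSE, P1)$avoids_as_anti) # 30 uM: no
  expect_true(call_binding(30001, FALSE, P1)$avoids_as_anti)
  expect_true(call_binding(30000, TRUE, P1)$avoids_as_anti)   # censored
  expect_false(call_binding(30000, TRUE, P1)$binds_as_pro)
  mid <- call_binding(20000, FALSE, P1)
  expect_false(mid$binds_as_pro)
  expect_false(mid$avoids_as_anti)
  expect_error(call_binding(-5, FALSE, P1), "positive")
  # idempotence: calling twice gives the identical call
  expect_identical(call_binding(1234, FALSE, P1), call_binding(1234, FALSE, P1))
})

test_that("bundled rubrics transcribe the published point schedules", {
  expect_equal(P1$bind_criteria[[2]]$points, c(1, 3, 9))
  expect_equal(P1$avoid_criteria[[2]]$points, c(1, 2, 3, 4))
  expect_true(P1$avoid_criteria[[1]]$starred[1])          # MKNK1*
  expect_equal(unname(P1$bonus), c(2, 2, 3))
  expect_equal(unname(P2$bonus[c("novelty", "patent", "druglike", "cns")]),
               c(2, 2, 3, 3))
  expect_true(all(P2$bind_criteria[[1]]$starred))          # AURKA*
  expect_equal(polypharm:::rubric_max_target_points(P1), 21)
  expect_error(
    target_rubric(1, list(list(targets = c("A", "B"), points = c(3, 1))),
                  list()),
    "non-decreasing")
})

# aux evidence passing every bonus; reference far from any test compound
ref_far <- aux_evidence(novelty_reference = list(manual_fp(1500:1600)),
                        patent_hits = 0)

test_that("worked scoring examples reproduce the published point values", {
  panel <- censored_panel("cpd", P1)
  druglike_mol <- "CCOc1ccccc1"  # small, Lipinski-clean, TPSA < 75

  # BRAF+SRC+S6K bound, nothing else: that criterion contributes 9
  p <- set_kd(panel, "cpd", c(BRAF = 100, SRC = 200, S6K = 300))
  card <- score_problem("cpd", p, P1, ref_far, mol = druglike_mol)
  crit <- card$criteria[card$criteria$criterion == "binds BRAF/SRC/S6K", ]
  expect_equal(crit$points, 9)

  # all four of TTK/ERK8/PDK1/PAK3 avoided (censored) with >=1 pro-target
  # bound: the avoid criterion contributes 4
  avoid4 <- card$criteria[card$criteria$criterion == "avoids TTK/ERK8/PDK1/PAK3", ]
  expect_equal(avoid4$points, 4)

  # a compound failing every binding criterion but passing novelty, patent
  # and drug-likeness scores exactly 7
  card0 <- score_problem("cpd", panel, P1, ref_far, mol = druglike_mol)
  expect_equal(card0$target_points, 0)
  expect_equal(card0$problem_total, 7)
})

test_that("avoidance earns nothing without at least one pro-target hit", {
  panel <- censored_panel("cpd", P1)   # censored everywhere: avoids all
  card <- score_problem("cpd", panel, P1, ref_far, mol = "CCO")
  expect_equal(card$target_points, 0)
  # one pro-target hit unlocks the avoid criteria
  p <- set_kd(panel, "cpd", c(BRAF = 500))
  card2 <- score_problem("cpd", p, P1, ref_far, mol = "CCO")
  expect_equal(card2$target_points, 1 + 3 + 4)
})

test_that("bonus criteria implement their published cutoffs", {
  desc_pass <- descriptors("CCOc1ccccc1")
  # novelty boundary: max Tc = 0.4 fails (strict <), 0.39 passes
  fp <- manual_fp(1:39)
  ref40 <- aux_evidence(novelty_reference = list(manual_fp(c(1, 2, 4, 5))))
  # craft Tc exactly 0.4: |inter| = 2, |union| = 5
  fp40 <- manual_fp(1:3)
  b <- evaluate_bonus(fp40, ref40, desc_pass, P1)
  expect_false(b$passed[b$criterion == "novelty"])
  ref_low <- aux_evidence(novelty_reference = list(manual_fp(c(1, 101:104))))
  # Tc = 1/9 < 0.4
  b2 <- evaluate_bonus(manual_fp(c(1, 301:304)), ref_low, desc_pass, P1)
  expect_true(b2$passed[b2$criterion == "novelty"])
  # identical to a reference active: novelty false
  b3 <- evaluate_bonus(manual_fp(1:10),
                       aux_evidence(novelty_reference = list(manual_fp(1:10))),
                       desc_pass, P1)
  expect_false(b3$passed[b3$criterion == "novelty"])
  # empty reference: vacuous pass, with a warning
  expect_warning(
    b4 <- evaluate_bonus(fp, aux_evidence(), desc_pass, P1),
    "vacuous")
  expect_true(b4$passed[b4$criterion == "novelty"])
  # patent: < 2 hits
  b5 <- evaluate_bonus(fp, aux_evidence(list(manual_fp(1500)), patent_hits = 1),
                       desc_pass, P1)
  expect_true(b5$passed[b5$criterion == "patent"])
  b6 <- evaluate_bonus(fp, aux_evidence(list(manual_fp(1500)), patent_hits = 2),
                       desc_pass, P1)
  expect_false(b6$passed[b6$criterion == "patent"])
  # drug-likeness: 3 of 4 Lipinski criteria suffice
  d3 <- desc_pass; d3$mw <- 600
  b7 <- evaluate_bonus(fp, ref40, d3, P1)
  expect_true(b7$passed[b7$criterion == "druglike"])
  d2 <- d3; d2$clogp <- 6
  b8 <- evaluate_bonus(fp, ref40, d2, P1)
  expect_false(b8$passed[b8$criterion == "druglike"])
  # CNS (problem 2 only): TPSA < 75
  dcns <- desc_pass; dcns$tpsa <- 74.9
  b9 <- evaluate_bonus(fp, ref40, dcns, P2)
  expect_true(b9$passed[b9$criterion == "cns"])
  dcns$tpsa <- 75
  b10 <- evaluate_bonus(fp, ref40, dcns, P2)
  expect_false(b10$passed[b10$criterion == "cns"])
  expect_false("cns" %in% evaluate_bonus(fp, ref40, desc_pass, P1)$criterion)
})

test_that("star modes differ exactly as documented", {
  panel <- censored_panel("cpd", P2)
  # binds AURKA + FGFR1 + STK11, fails starred PAK1; avoids all anti
  p <- set_kd(panel, "cpd", c(AURKA = 50, FGFR1 = 900, STK11 = 900))
  per <- score_problem("cpd", p, P2, ref_far, mol = "CCO",
                       star_mode = "per_criterion")
  expect_true("PAK1" %in% per$starred_failed)
  expect_equal(per$target_points, 5 + 3 + 3 + 3 + 1)  # AURKA + FGFR1/STK11 + avoids
  gate <- score_problem("cpd", p, P2, ref_far, mol = "CCO",
                        star_mode = "gate_all")
  expect_equal(gate$target_points, 0)
  expect_equal(gate$bonus_points, per$bonus_points)
})

test_that("score cards are internally consistent on many random panels", {
  targets <- polypharm:::rubric_targets(P1)
  fp <- fingerprint("CCOc1ccccc1", "ecfp6_2048")
  desc <- descriptors("CCOc1ccccc1")
  set.seed(42)
  for (i in 1:1000) {
    kd <- matrix(10^stats::runif(length(targets), 1, 5.2), 1,
                 dimnames = list("x", targets))
    cen <- matrix(stats::runif(length(targets)) < 0.3, 1,
                  dimnames = list("x", targets))
    pan <- kd_panel(kd, cen)
    card <- score_problem("x", pan, P1, ref_far, fp = fp, desc = desc)
    expect_equal(card$problem_total,
                 sum(card$criteria$points) + sum(card$bonus$points))
    expect_true(all(card$criteria$points >= 0))
    expect_true(all(card$criteria$points <= card$criteria$max_points))
  }
})

test_that("lowering a pro-target Kd never decreases the problem total", {
  fp <- fingerprint("CCOc1ccccc1", "ecfp6_2048")
  desc <- descriptors("CCOc1ccccc1")
  targets <- polypharm:::rubric_targets(P1)
  pro <- c("RET_M918T", "BRAF", "SRC", "S6K")
  set.seed(7)
  for (i in 1:60) {
    kd <- matrix(10^stats::runif(length(targets), 2, 5.3), 1,
                 dimnames = list("x", targets))
    cen <- matrix(FALSE, 1, length(targets), dimnames = list("x", targets))
    pan <- kd_panel(kd, cen)
    base <- score_problem("x", pan, P1, ref_far, fp = fp, desc = desc)
    tg <- sample(pro, 1)
    kd2 <- kd; kd2["x", tg] <- kd["x", tg] / 100
    low <- score_problem("x", kd_panel(kd2, cen), P1, ref_far,
                         fp = fp, desc = desc)
    expect_gte(low$problem_total, base$problem_total)
    # adding an anti-target hit never increases the total
    anti <- sample(c("MKNK1", "TTK", "ERK8", "PDK1", "PAK3"), 1)
    kd3 <- kd; kd3["x", anti] <- 100
    hit <- score_problem("x", kd_panel(kd3, cen), P1, ref_far,
                         fp = fp, desc = desc)
    expect_lte(hit$problem_total, base$problem_total)
  }
})

test_that("final aggregation reproduces the published scoreboard", {
  scoreboard <- data.frame(
    team = c("Zhaoping Xiong", "DMIS_MTD", "Lasige-BioISI", "SuperModels",
             "Huiyuan Chen", "Masahiro Mochizuki", "David Koes",
             "Gregory Koytiger", "UM-BISBII", "Stratified"),
    p1 = c(16, 16, 7, 7, 7, 7, 7, 7, 8, 7),
    p2 = c(11, 9, 7, 7, 7, 7, 7, 7, NA, NA),
    interactome = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE),
    final = c(28, 25, 15, 14, 14, 14, 14, 14, 8, 7))
  got <- aggregate_final(scoreboard$p1, scoreboard$p2, scoreboard$interactome)
  expect_equal(got, scoreboard$final)
  expect_equal(aggregate_final(0, 0, FALSE), 0)
  expect_error(aggregate_final(-1, 0, FALSE), ">= 0")
})

test_that("a rubric target missing from the panel is a hard error", {
  kd <- matrix(1000, 1, 2, dimnames = list("x", c("BRAF", "SRC")))
  pan <- kd_panel(kd)
  expect_error(score_problem("x", pan, P1, ref_far, mol = "CCO"),
               "lacks rubric target")
  expect_error(score_problem("nope", censored_panel("x", P1), P1, ref_far,
                             mol = "CCO"),
               "not in Kd panel")
})
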