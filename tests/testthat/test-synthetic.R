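# The synthetic-challenge generator: determinism, planted structure,
# planted roles and the reference-active set.

cfg_small <- generator_config(seed = 7, library_size = 24, n_teams = 10,
                              per_team = 2)

test_that("generated libraries are valid, unique and deterministic", {
  lib <- generate_library(cfg_small)
  expect_equal(nrow(lib), 24)
  keys <- vapply(lib$smiles, canonical_key, character(1))
  expect_equal(anyDuplicated(keys), 0)
  for (s in lib$smiles) expect_s3_class(parse_smiles(s), "mol_graph")
  expect_identical(lib, generate_library(cfg_small))
  # a different seed reshuffles
  expect_false(identical(lib, generate_library(generator_config(
    seed = 8, library_size = 24, n_teams = 10, per_team = 2))))
  # scaffold families separate: max between-family Tc < min within-family Tc
  tc <- similarity_matrix(lib$smiles)
  same <- outer(lib$family, lib$family, "==")
  within <- tc[same & upper.tri(tc)]
  between <- tc[!same & upper.tri(tc)]
  expect_lt(max(between), min(within))
})

test_that("planted panel roles respect their Kd constraints", {
  lib <- generate_library(cfg_small)
  rubric <- challenge_rubric(1)
  gp <- generate_kd_panel(lib, rubric, cfg_small)
  panel <- gp$panel
  pro <- c("RET_M918T", "BRAF", "SRC", "S6K")
  anti <- c("MKNK1", "TTK", "ERK8", "PDK1", "PAK3")
  ideal <- names(gp$roles)[gp$roles == "ideal"]
  near <- names(gp$roles)[gp$roles == "near_miss"]
  expect_true(all(panel$kd_nM[ideal, pro] <= rubric$pro_bind_nM))
  expect_false(any(panel$censored[ideal, pro]))
  expect_true(all(panel$censored[ideal, anti]))
  expect_equal(sum(!panel$censored[near, pro]), 1)
  # an ideal profile earns the rubric's maximum target-based points
  # (oracle: exhaustive best over the schedules)
  ref <- aux_evidence(novelty_reference = list(manual_fp(1500:1600)))
  card <- score_problem(ideal, panel, rubric, ref,
                        mol = lib$smiles[lib$id == ideal])
  expect_equal(card$target_points, oracle_max_target_points(rubric))
  # an all-censored background compound scores bonus-only points
  bg <- names(gp$roles)[gp$roles == "background"]
  bg_all_cen <- bg[vapply(bg, function(b) all(panel$censored[b, ]),
                          logical(1))][1]
  card_bg <- score_problem(bg_all_cen, panel, rubric, ref,
                           mol = lib$smiles[lib$id == bg_all_cen])
  expect_equal(card_bg$target_points, 0)
  expect_equal(card_bg$problem_total, card_bg$bonus_points)
  # determinism of the whole panel
  gp2 <- generate_kd_panel(lib, rubric, cfg_small)
  expect_identical(gp$panel$kd_nM, gp2$panel$kd_nM)
})

test_that("background censoring matches the configured fraction", {
  cfg <- generator_config(seed = 5, library_size = 120, n_teams = 10,
                          censor_frac = 0.85)
  lib <- generate_library(cfg)
  rubric <- challenge_rubric(1)
  gp <- generate_kd_panel(lib, rubric, cfg)
  bg <- names(gp$roles)[gp$roles == "background"]
  cells <- gp$panel$censored[bg, ]
  expect_gt(length(cells), 1000)
  expect_equal(mean(cells), 0.85, tolerance = 0.05)
})

test_that("submission sets round-trip through YAML and plant the duplicate", {
  lib <- generate_library(cfg_small)
  subs <- generate_submissions(lib, cfg_small)
  expect_equal(nrow(subs$entries), 10 * 2)
  dd <- dedup_top_ranked(subs)
  expect_equal(dd$n_unique, 9)      # 10 teams, one planted rank-1 duplicate
  # the duplicate is written as a different SMILES string
  top <- subs$entries[subs$entries$rank == 1, ]
  t1 <- top$smiles[top$team == "Team_01"]
  t2 <- top$smiles[top$team == "Team_02"]
  expect_false(t1 == t2)
  expect_identical(canonical_key(t1), canonical_key(t2))
  # without the planted duplicate the count equals the team count
  cfg_nodup <- generator_config(seed = 7, library_size = 24, n_teams = 10,
                                per_team = 2, duplicate_pair = FALSE)
  expect_equal(dedup_top_ranked(
    generate_submissions(lib, cfg_nodup))$n_unique, 10)
  # YAML round trip is lossless
  dir <- withr::local_tempdir()
  write_submissions(subs, dir)
  back <- read_submissions(dir)
  a <- subs$entries[order(subs$entries$team, subs$entries$rank), ]
  b <- back$entries[order(back$entries$team, back$entries$rank), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("reference actives separate novelty by scaffold family", {
  # default study conditions: 50-compound library, 12 reference actives
  cfg_ref <- generator_config(seed = 7)
  lib <- generate_library(cfg_ref)
  ref <- generate_reference_actives(lib, cfg_ref)
  expect_equal(length(ref$smiles), cfg_ref$n_ref)
  aux <- aux_evidence(novelty_reference = ref$fps)
  desc <- descriptors("CCO")
  # a reference compound itself: Tc = 1, novelty false
  fp_self <- fingerprint(ref$smiles[1], "ecfp6_2048")
  b <- evaluate_bonus(fp_self, aux, desc, challenge_rubric(1))
  expect_false(b$passed[b$criterion == "novelty"])
  # same-family candidate not in the reference: max Tc >= 0.4 -> fails
  fam_members <- lib$smiles[lib$family == ref$family &
                            !lib$smiles %in% ref$smiles]
  tc_same <- similarity_matrix(fam_members[1], ref$smiles,
                               dialect = "ecfp6_2048")
  expect_gte(max(tc_same), 0.4)
  b2 <- evaluate_bonus(fingerprint(fam_members[1], "ecfp6_2048"), aux,
                       desc, challenge_rubric(1))
  expect_false(b2$passed[b2$criterion == "novelty"])
  # other-family candidate: max Tc < 0.4 -> passes
  other <- lib$smiles[lib$family != ref$family][1]
  tc_other <- similarity_matrix(other, ref$smiles, dialect = "ecfp6_2048")
  expect_lt(max(tc_other), 0.4)
  b3 <- evaluate_bonus(fingerprint(other, "ecfp6_2048"), aux, desc,
                       challenge_rubric(1))
  expect_true(b3$passed[b3$criterion == "novelty"])
})

test_that("whole instances are byte-identical across reruns of one seed", {
  cfg <- generator_config(seed = 13, library_size = 15, n_teams = 6,
                          per_team = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_challenge(cfg, dir = d1)
  generate_challenge(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
})
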