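# The challenge scoring engine: binding calls from Kd panels, rubric points,
# bonus criteria and final aggregation.
#
# Scoring rules implemented (defaults mirror the published challenge rubric):
#   * "binding" a pro-target  = Kd <= pro_bind_nM  (10 uM) and not censored.
#   * "avoiding" an anti-target = censored or Kd > anti_avoid_nM (30 uM).
#     Values in (10, 30] uM neither bind nor avoid.
#   * Each bind/avoid criterion carries a point schedule mapping the number
#     of satisfied targets to points.
#   * Avoid-criterion points are only awarded when the compound binds at
#     least one pro-target: the challenge scoreboard shows non-binding
#     compounds scoring bonus-only totals, so avoidance alone earns nothing.
#   * Bonuses: novelty (max ECFP6 Tanimoto vs reference actives < 0.4),
#     patentability (patent_hits < 2), drug-likeness (>= 3 of the 4 Lipinski
#     criteria), and - when the rubric includes it - CNS penetration
#     (TPSA < 75 A^2).
#   * Starred targets: star_mode = "per_criterion" (default) awards each
#     criterion independently and reports failed starred requirements;
#     "gate_all" zeroes all target-based points of the problem when any
#     starred requirement fails.

#' Construct a scoring rubric
#'
#' @param problem problem identifier (e.g. 1 or 2).
#' @param bind_criteria,avoid_criteria lists of criteria; each criterion is a
#'   list with `targets` (character), `points` (numeric vector, points for
#'   1..k satisfied targets, non-decreasing) and optional `starred` (logical,
#'   per target).
#' @param bonus named numeric vector; recognised names `novelty`, `patent`,
#'   `druglike`, `cns` (omit `cns` for rubrics without it).
#' @param pro_bind_nM,anti_avoid_nM binding-call thresholds in nM.
#' @param novelty_tc,cns_tpsa bonus thresholds (max reference Tanimoto,
#'   TPSA ceiling).
#' @return an object of class `target_rubric`.
#' @export
target_rubric <- function(problem, bind_criteria, avoid_criteria,
                          bonus = c(novelty = 2, patent = 2, druglike = 3),
                          pro_bind_nM = 10000, anti_avoid_nM = 30000,
                          novelty_tc = 0.4, cns_tpsa = 75) {
  stopifnot(pro_bind_nM > 0, anti_avoid_nM > 0, pro_bind_nM <= anti_avoid_nM)
  norm <- function(crit, what) {
    lapply(crit, function(cr) {
      stopifnot(is.character(cr$targets), length(cr$targets) >= 1)
      pts <- as.numeric(cr$points)
      if (length(pts) != length(cr$targets))
        stop(sprintf("%s criterion (%s): need one point value per count 1..%d",
                     what, paste(cr$targets, collapse = ","),
                     length(cr$targets)), call. = FALSE)
      if (is.unsorted(pts))
        stop("point schedules must be non-decreasing in count", call. = FALSE)
      starred <- cr$starred
      if (is.null(starred)) starred <- rep(FALSE, length(cr$targets))
      if (length(starred) == 1) starred <- rep(starred, length(cr$targets))
      list(targets = cr$targets, points = pts, starred = as.logical(starred))
    })
  }
  structure(list(problem = problem,
                 bind_criteria = norm(bind_criteria, "bind"),
                 avoid_criteria = norm(avoid_criteria, "avoid"),
                 bonus = bonus,
                 pro_bind_nM = pro_bind_nM, anti_avoid_nM = anti_avoid_nM,
                 novelty_tc = novelty_tc, cns_tpsa = cns_tpsa),
            class = "target_rubric")
}

rubric_targets <- function(rubric) {
  unique(unlist(c(lapply(rubric$bind_criteria, `[[`, "targets"),
                  lapply(rubric$avoid_criteria, `[[`, "targets"))))
}

# maximum target-based points obtainable under the rubric
rubric_max_target_points <- function(rubric) {
  s <- function(cr) max(cr$points)
  sum(vapply(rubric$bind_criteria, s, numeric(1))) +
    sum(vapply(rubric$avoid_criteria, s, numeric(1)))
}

#' Read a rubric from YAML
#'
#' Schema: `problem`, `thresholds: {pro_bind_nM, anti_avoid_nM, novelty_tc,
#' cns_tpsa}`, `bind_criteria` / `avoid_criteria` (lists with `targets`,
#' `points`, optional `starred`), `bonus` (named point values). Bundled
#' rubrics transcribing the challenge's scoring table ship in
#' `inst/extdata/rubrics/`.
#'
#' @param path YAML file path.
#' @return a `target_rubric`.
#' @export
read_rubric <- function(path) {
  if (!file.exists(path)) stop("rubric file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  th <- y$thresholds
  args <- list(problem = y$problem,
               bind_criteria = y$bind_criteria,
               avoid_criteria = y$avoid_criteria,
               bonus = unlist(y$bonus))
  if (!is.null(th$pro_bind_nM)) args$pro_bind_nM <- th$pro_bind_nM
  if (!is.null(th$anti_avoid_nM)) args$anti_avoid_nM <- th$anti_avoid_nM
  if (!is.null(th$novelty_tc)) args$novelty_tc <- th$novelty_tc
  if (!is.null(th$cns_tpsa)) args$cns_tpsa <- th$cns_tpsa
  do.call(target_rubric, args)
}

#' Bundled challenge rubric
#'
#' @param problem 1 (RET-driven cancer) or 2 (tauopathy).
#' @return a `target_rubric`.
#' @export
challenge_rubric <- function(problem) {
  stopifnot(problem %in% c(1, 2))
  read_rubric(system.file("extdata", "rubrics",
                          sprintf("problem%d.yaml", problem),
                          package = "polypharm", mustWork = TRUE))
}

#' Classify one Kd measurement against the rubric thresholds
#'
#' @param kd_nM dissociation constant in nM (the censoring bound when
#'   censored).
#' @param censored TRUE when the assay reported no hit up to its detection
#'   limit.
#' @param rubric a `target_rubric` (thresholds are taken from it).
#' @return a list with `binds_as_pro`, `avoids_as_anti`, `kd_nM`, `censored`.
#' @examples
#' call_binding(5000, FALSE, challenge_rubric(1))$binds_as_pro   # TRUE
#' @export
call_binding <- function(kd_nM, censored = FALSE, rubric) {
  if (!censored && (!is.finite(kd_nM) || kd_nM <= 0))
    stop("kd_nM must be positive (or the measurement censored)",
         call. = FALSE)
  binds <- !censored && kd_nM <= rubric$pro_bind_nM
  avoids <- censored || kd_nM > rubric$anti_avoid_nM
  list(binds_as_pro = binds, avoids_as_anti = avoids,
       kd_nM = kd_nM, censored = censored)
}

#' Bundle auxiliary (non-assay) scoring evidence
#'
#' @param novelty_reference reference-active set for the novelty check:
#'   a list of `chem_fp` ECFP6 fingerprints, a character vector of SMILES,
#'   or NULL/empty (novelty passes vacuously, with a warning downstream).
#' @param patent_hits number of prior-art hits reported by an external
#'   patent search (supplied as data; no live query is performed).
#' @param interactome did the team take part in the interactome exercise.
#' @return an `aux_evidence` object.
#' @export
aux_evidence <- function(novelty_reference = NULL, patent_hits = 0L,
                         interactome = FALSE) {
  stopifnot(patent_hits >= 0)
  if (is.character(novelty_reference))
    novelty_reference <- fingerprint_set(as.list(novelty_reference),
                                         "ecfp6_2048")
  structure(list(novelty_reference = novelty_reference,
                 patent_hits = as.integer(patent_hits),
                 interactome = isTRUE(interactome)),
            class = "aux_evidence")
}

#' Evaluate the bonus criteria for one compound
#'
#' Novelty: maximum ECFP6 Tanimoto against the reference actives strictly
#' below the rubric threshold (0.4). Patentability: fewer than 2 reported
#' patent hits. Drug-likeness: at least 3 of the 4 Lipinski criteria
#' (MW <= 500, cLogP <= 5, HBD <= 5, HBA <= 10). CNS (only when the rubric
#' awards it): TPSA strictly below 75 A^2.
#'
#' @param fp the compound's ECFP6 fingerprint (`chem_fp`).
#' @param aux an `aux_evidence` object.
#' @param desc the compound's `descriptor_set`.
#' @param rubric a `target_rubric`.
#' @return data frame with one row per bonus criterion: `criterion`,
#'   `passed`, `points`, `detail`.
#' @export
evaluate_bonus <- function(fp, aux, desc, rubric) {
  stopifnot(inherits(aux, "aux_evidence"))
  bonus <- rubric$bonus
  rows <- list()
  if ("novelty" %in% names(bonus)) {
    ref <- aux$novelty_reference
    if (is.null(ref) || length(ref) == 0) {
      warning("empty novelty reference set: novelty passes vacuously",
              call. = FALSE)
      max_tc <- NA_real_
      passed <- TRUE
    } else {
      if (fp$dialect != "ecfp6_2048")
        stop("novelty check requires an ecfp6_2048 fingerprint", call. = FALSE)
      max_tc <- max(vapply(ref, function(r) tanimoto(fp, r), numeric(1)))
      passed <- max_tc < rubric$novelty_tc
    }
    rows$novelty <- data.frame(criterion = "novelty", passed = passed,
                               points = if (passed) bonus[["novelty"]] else 0,
                               detail = sprintf("max reference Tc = %s",
                                                format(max_tc, digits = 3)))
  }
  if ("patent" %in% names(bonus)) {
    passed <- aux$patent_hits < 2
    rows$patent <- data.frame(criterion = "patent", passed = passed,
                              points = if (passed) bonus[["patent"]] else 0,
                              detail = sprintf("%d patent hits",
                                               aux$patent_hits))
  }
  if ("druglike" %in% names(bonus)) {
    crit <- c(mw = desc$mw <= 500, clogp = desc$clogp <= 5,
              hbd = desc$hbd <= 5, hba = desc$hba <= 10)
    passed <- sum(crit) >= 3
    rows$druglike <- data.frame(
      criterion = "druglike", passed = passed,
      points = if (passed) bonus[["druglike"]] else 0,
      detail = sprintf("%d/4 Lipinski criteria", sum(crit)))
  }
  if ("cns" %in% names(bonus)) {
    passed <- desc$tpsa < rubric$cns_tpsa
    rows$cns <- data.frame(criterion = "cns", passed = passed,
                           points = if (passed) bonus[["cns"]] else 0,
                           detail = sprintf("TPSA = %.1f", desc$tpsa))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score one compound against a problem rubric
#'
#' Produces the full per-criterion breakdown: target-based points from the
#' Kd panel, bonus points, starred-requirement status and the problem total.
#'
#' @param compound compound identifier (must be a row of `panel`).
#' @param panel a `kd_panel` (see [kd_panel()]); must cover every rubric
#'   target.
#' @param rubric a `target_rubric`.
#' @param aux an `aux_evidence` object.
#' @param mol the compound structure (`mol_graph` or SMILES); required for
#'   the novelty / drug-likeness / CNS bonuses unless both `fp` and `desc`
#'   are supplied.
#' @param fp,desc optional precomputed ECFP6 fingerprint and descriptor set.
#' @param star_mode `"per_criterion"` (default) or `"gate_all"`.
#' @return a `score_card` object.
#' @export
score_problem <- function(compound, panel, rubric, aux,
                          mol = NULL, fp = NULL, desc = NULL,
                          star_mode = c("per_criterion", "gate_all")) {
  star_mode <- match.arg(star_mode)
  stopifnot(inherits(rubric, "target_rubric"))
  targets <- rubric_targets(rubric)
  missing_t <- setdiff(targets, colnames(panel$kd_nM))
  if (length(missing_t) > 0)
    stop("Kd panel lacks rubric target(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  if (!compound %in% rownames(panel$kd_nM))
    stop("compound not in Kd panel: ", compound, call. = FALSE)

  calls <- lapply(targets, function(tg) {
    call_binding(panel$kd_nM[compound, tg], panel$censored[compound, tg],
                 rubric)
  })
  names(calls) <- targets
  binds <- vapply(calls, `[[`, logical(1), "binds_as_pro")
  avoids <- vapply(calls, `[[`, logical(1), "avoids_as_anti")
  any_pro_bound <- any(binds[unique(unlist(
    lapply(rubric$bind_criteria, `[[`, "targets")))])

  starred_failed <- character()
  crit_rows <- list()
  for (k in seq_along(rubric$bind_criteria)) {
    cr <- rubric$bind_criteria[[k]]
    sat <- cr$targets[binds[cr$targets]]
    pts <- if (length(sat) == 0) 0 else cr$points[length(sat)]
    fail_star <- cr$targets[cr$starred & !binds[cr$targets]]
    starred_failed <- c(starred_failed, fail_star)
    crit_rows[[length(crit_rows) + 1L]] <- data.frame(
      criterion = sprintf("binds %s", paste(cr$targets, collapse = "/")),
      type = "bind", points = pts, max_points = max(cr$points),
      satisfied = paste(sat, collapse = ";"),
      starred_failed = paste(fail_star, collapse = ";"))
  }
  for (k in seq_along(rubric$avoid_criteria)) {
    cr <- rubric$avoid_criteria[[k]]
    sat <- cr$targets[avoids[cr$targets]]
    pts <- if (length(sat) == 0 || !any_pro_bound) 0
           else cr$points[length(sat)]
    fail_star <- cr$targets[cr$starred & !avoids[cr$targets]]
    starred_failed <- c(starred_failed, fail_star)
    crit_rows[[length(crit_rows) + 1L]] <- data.frame(
      criterion = sprintf("avoids %s", paste(cr$targets, collapse = "/")),
      type = "avoid", points = pts, max_points = max(cr$points),
      satisfied = paste(sat, collapse = ";"),
      starred_failed = paste(fail_star, collapse = ";"))
  }
  criteria <- do.call(rbind, crit_rows)
  if (star_mode == "gate_all" && length(starred_failed) > 0)
    criteria$points <- 0

  needs_chem <- any(c("novelty", "druglike", "cns") %in% names(rubric$bonus))
  if (needs_chem && (is.null(fp) || is.null(desc))) {
    if (is.null(mol))
      stop("supply `mol` (or precomputed `fp` and `desc`) for the bonus ",
           "criteria", call. = FALSE)
    mol <- as_mol(mol)
    if (is.null(fp)) fp <- fingerprint(mol, "ecfp6_2048")
    if (is.null(desc)) desc <- descriptors(mol)
  }
  bonus <- evaluate_bonus(fp, aux, desc, rubric)
  total <- sum(criteria$points) + sum(bonus$points)
  structure(list(compound = compound, problem = rubric$problem,
                 criteria = criteria, bonus = bonus,
                 starred_failed = unique(starred_failed),
                 star_mode = star_mode,
                 target_points = sum(criteria$points),
                 bonus_points = sum(bonus$points),
                 problem_total = total),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %s (problem %s, star_mode %s)\n",
              x$compound, x$problem, x$star_mode))
  print(x$criteria[, c("criterion", "points", "max_points", "satisfied")],
        row.names = FALSE)
  print(x$bonus[, c("criterion", "passed", "points", "detail")],
        row.names = FALSE)
  if (length(x$starred_failed))
    cat("starred requirements failed:",
        paste(x$starred_failed, collapse = ", "), "\n")
  cat(sprintf("problem total: %g (targets %g + bonus %g)\n",
              x$problem_total, x$target_points, x$bonus_points))
  invisible(x)
}

#' Aggregate problem scores into the final challenge score
#'
#' `final = P1 + P2 + interactome bonus`. The interactome bonus defaults to
#' 1 point, the value consistent with the published scoreboard; `NA` problem
#' scores (team did not enter that problem) count as 0.
#'
#' @param p1_points,p2_points non-negative problem scores (NA allowed).
#' @param interactome logical.
#' @param interactome_bonus points for interactome participation.
#' @return the final score (numeric).
#' @examples
#' aggregate_final(16, 11, TRUE)   # 28
#' @export
aggregate_final <- function(p1_points, p2_points, interactome = FALSE,
                            interactome_bonus = 1) {
  p1 <- ifelse(is.na(p1_points), 0, p1_points)
  p2 <- ifelse(is.na(p2_points), 0, p2_points)
  if (any(p1 < 0 | p2 < 0)) stop("problem scores must be >= 0", call. = FALSE)
  p1 + p2 + ifelse(interactome, interactome_bonus, 0)
}
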