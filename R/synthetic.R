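# Deterministic generator of complete synthetic challenge instances.
#
# Molecule libraries are built by decorating bundled scaffold cores (distinct
# ring systems) with family-specific substituent sets, so that similarity
# within a scaffold family is high and across families low - the structure
# the network and novelty analyses need. Kd panels plant compound roles:
#   ideal     - binds every pro-target (Kd ~ 100 nM), censored on all
#               anti-targets; the profile an ideal polypharmacology lead
#               would show.
#   near_miss - binds exactly one pro-target (~5 uM), censored elsewhere;
#               emulates a compound that hits one kinase but no more.
#   background- censored everywhere except a configurable fraction of cells
#               drawn in the dead zone (10-30 uM: neither binding nor
#               avoiding).
# Kd noise is multiplicative log-normal (assay dilution series structure);
# draws that would cross a role's threshold are redrawn so roles stay intact.
# Every artifact uses its own named RNG stream derived from the master seed,
# so adding one output never shifts another.

SCAFFOLD_FAMILIES <- list(
  quinazoline = list(
    template = "c1cc2c(cc1{A})ncnc2Nc1ccc{B}c{C}c1",
    subs = list(A = c("", "(F)", "(Cl)", "(OC)", "(C)"),
                B = c("", "(F)", "(Cl)", "(O)", "(OC)", "(N)"),
                C = c("", "(C)", "(OC)"))),
  sulfonamide = list(
    template = "O=S(=O)(N1CCC{A}CC1)CC{B}C{C}",
    subs = list(A = c("", "(C)", "(O)", "(CC)", "(N)"),
                B = c("", "(C)", "(O)"),
                C = c("", "C", "CC", "O", "N"))),
  chromenone = list(
    template = "O=C1C=C(c2ccc{A}cc2)Oc2cc{B}ccc12",
    subs = list(A = c("", "(F)", "(Cl)", "(O)", "(OC)", "(C)", "(N)"),
                B = c("", "(O)", "(OC)", "(C)", "(Cl)")))
)

# stable 31-bit stream seed from master seed + stream name
stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) %% 65011 + 1) * 32749 + h) %% 2147483647L
}

#' Generator configuration
#'
#' Defaults mirror the challenge's shapes: 10 teams of up to 5 ranked
#' predictions, a 30 uM assay ceiling, and a compound library split across
#' chemically distinct scaffold families.
#'
#' @param seed master integer seed; every artifact derives its own stream.
#' @param library_size number of library compounds.
#' @param n_teams number of submitting teams.
#' @param per_team ranked compounds per team (challenge template: 5).
#' @param problem which bundled rubric the instance targets (1 or 2).
#' @param censor_frac fraction of background panel cells that are censored.
#' @param sigma_log10 log10-scale standard deviation of Kd noise.
#' @param censor_bound_nM assay detection ceiling.
#' @param n_ref size of the synthetic reference-active set.
#' @param duplicate_pair plant one rank-1 duplicate written as two distinct
#'   SMILES forms in two different teams.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1, library_size = 50, n_teams = 10,
                             per_team = 5, problem = 1, censor_frac = 0.9,
                             sigma_log10 = 0.2, censor_bound_nM = 30000,
                             n_ref = 12, duplicate_pair = TRUE) {
  stopifnot(library_size >= n_teams, per_team <= SUBMISSION_MAX_RANK,
            censor_frac >= 0, censor_frac <= 1, sigma_log10 >= 0)
  structure(list(seed = as.integer(seed), library_size = library_size,
                 n_teams = n_teams, per_team = per_team, problem = problem,
                 censor_frac = censor_frac, sigma_log10 = sigma_log10,
                 censor_bound_nM = censor_bound_nM, n_ref = n_ref,
                 duplicate_pair = duplicate_pair),
            class = "generator_config")
}

expand_family <- function(family_name) {
  fam <- SCAFFOLD_FAMILIES[[family_name]]
  grids <- expand.grid(fam$subs, stringsAsFactors = FALSE)
  smiles <- apply(grids, 1, function(row) {
    s <- fam$template
    for (slot in names(fam$subs))
      s <- sub(paste0("{", slot, "}"), row[[slot]], s, fixed = TRUE)
    s
  })
  unique(smiles)
}

#' Generate a synthetic compound library
#'
#' Decorated scaffold variants, deduplicated by canonical identity, with
#' family labels. Deterministic: the same config always yields the same
#' SMILES list.
#'
#' @param config a `generator_config`.
#' @return data frame with columns `id`, `smiles` (canonical), `family`.
#' @export
generate_library <- function(config = generator_config()) {
  rng <- local_rng(stream_seed(config$seed, "library"))
  on.exit(rng())
  fams <- names(SCAFFOLD_FAMILIES)
  pool <- do.call(rbind, lapply(fams, function(f) {
    data.frame(smiles = expand_family(f), family = f)
  }))
  pool <- pool[sample(nrow(pool)), , drop = FALSE]
  # round-robin over families so every family is represented
  within_fam <- stats::ave(seq_len(nrow(pool)), pool$family, FUN = seq_along)
  pool <- pool[order(within_fam, match(pool$family, fams)), , drop = FALSE]
  if (config$library_size > nrow(pool))
    stop(sprintf("library_size %d exceeds enumerable space (%d)",
                 config$library_size, nrow(pool)), call. = FALSE)
  keys <- character(0)
  out <- list()
  for (i in seq_len(nrow(pool))) {
    if (length(out) >= config$library_size) break
    mol <- parse_smiles(pool$smiles[i])
    key <- canonical_key(mol)
    if (key %in% keys) next
    keys <- c(keys, key)
    out[[length(out) + 1L]] <- data.frame(
      id = sprintf("SYN%05d", length(out) + 1L),
      smiles = mol$smiles, family = pool$family[i])
  }
  if (length(out) < config$library_size)
    stop("scaffold space exhausted before reaching library_size",
         call. = FALSE)
  do.call(rbind, out)
}

# log-normal Kd around `center`, redrawn until it stays within (lo, hi]
draw_kd <- function(n, center, sigma_log10, lo = 0, hi = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- 10^(log10(center) + stats::rnorm(1, 0, sigma_log10))
      if (v > lo && v <= hi) { out[i] <- v; break }
    }
  }
  out
}

#' Generate a Kd panel with planted compound roles
#'
#' @param library data frame from [generate_library()].
#' @param rubric a `target_rubric` giving the kinase columns and thresholds.
#' @param config a `generator_config`.
#' @param roles optional named character vector compound id -> role
#'   (`"ideal"`, `"near_miss"`, `"background"`); by default the first
#'   library compound is ideal, the second a near-miss, the rest background.
#' @return list with `panel` (a `kd_panel`) and `roles`.
#' @export
generate_kd_panel <- function(library, rubric, config = generator_config(),
                              roles = NULL) {
  rng <- local_rng(stream_seed(config$seed, "panel"))
  on.exit(rng())
  targets <- rubric_targets(rubric)
  pro <- unique(unlist(lapply(rubric$bind_criteria, `[[`, "targets")))
  ids <- library$id
  if (is.null(roles)) {
    roles <- stats::setNames(rep("background", length(ids)), ids)
    roles[ids[1]] <- "ideal"
    if (length(ids) > 1) roles[ids[2]] <- "near_miss"
  }
  bad_roles <- setdiff(names(roles), ids)
  if (length(bad_roles) > 0)
    stop("role(s) reference unknown compound(s): ",
         paste(bad_roles, collapse = ", "), call. = FALSE)
  bound <- config$censor_bound_nM
  kd <- matrix(bound, length(ids), length(targets),
               dimnames = list(ids, targets))
  cen <- matrix(TRUE, length(ids), length(targets),
                dimnames = list(ids, targets))
  for (id in ids) {
    role <- roles[[id]]
    if (role == "ideal") {
      kd[id, pro] <- draw_kd(length(pro), 100, config$sigma_log10,
                             hi = rubric$pro_bind_nM)
      cen[id, pro] <- FALSE
    } else if (role == "near_miss") {
      # bind exactly one pro-target, from the multi-target criterion when
      # there is one (the profile: one kinase hit, everything else clean)
      nm_target <- if (length(rubric$bind_criteria) > 1)
        rubric$bind_criteria[[2]]$targets[1] else pro[1]
      kd[id, nm_target] <- draw_kd(1, 5000, config$sigma_log10,
                                   hi = rubric$pro_bind_nM)
      cen[id, nm_target] <- FALSE
    } else if (role == "background") {
      uncensor <- stats::runif(length(targets)) > config$censor_frac
      if (any(uncensor)) {
        # dead zone: measurable but neither binding nor avoiding
        kd[id, uncensor] <- draw_kd(sum(uncensor), 20000,
                                    config$sigma_log10,
                                    lo = rubric$pro_bind_nM,
                                    hi = rubric$anti_avoid_nM)
        cen[id, uncensor] <- FALSE
      }
    } else {
      stop("unknown role: ", role, call. = FALSE)
    }
  }
  list(panel = kd_panel(kd, cen, censor_bound_nM = bound), roles = roles)
}

# A second, distinct SMILES string for the same structure (used to plant the
# rank-1 duplicate): round-trip through InChI, falling back to an SDF
# round-trip; both re-emit the molecule in a different atom order.
alt_smiles_form <- function(smiles) {
  inchi <- ob_inchi(smiles)
  alt <- ob_convert("INCHI", "SMI", inchi)
  alt <- sub("\t.*$", "", strsplit(alt, "\n")[[1]][1])
  if (!is.na(alt) && nzchar(alt) && alt != smiles) return(alt)
  sdf <- ob_convert("SMI", "SDF", smiles)
  alt <- ob_convert("SDF", "SMI", sdf)
  alt <- sub("\t.*$", "", strsplit(alt, "\n")[[1]][1])
  if (!is.na(alt) && nzchar(alt) && alt != smiles) return(alt)
  smiles
}

#' Generate synthetic team submissions
#'
#' Assigns library compounds to teams (5 ranked predictions each) with
#' synthetic vendor identifiers and rationale text. With
#' `config$duplicate_pair`, teams 1 and 2 share the same rank-1 structure
#' written as two different SMILES forms - the situation the deduplication
#' step exists for.
#'
#' @param library data frame from [generate_library()].
#' @param config a `generator_config`.
#' @param dir optional directory: when given, per-team YAML files are
#'   written there.
#' @return a `submission_set` (invisibly also written to `dir` if given).
#' @export
generate_submissions <- function(library, config = generator_config(),
                                 dir = NULL) {
  rng <- local_rng(stream_seed(config$seed, "submissions"))
  on.exit(rng())
  n_needed <- config$n_teams * config$per_team
  dup <- config$duplicate_pair
  n_distinct <- n_needed - as.integer(dup)
  if (n_distinct > nrow(library))
    stop("library too small for requested submissions", call. = FALSE)
  if (dup && config$n_teams < 2)
    stop("duplicate_pair needs at least two teams", call. = FALSE)
  pick <- library[sample(nrow(library), n_distinct), , drop = FALSE]
  rows <- list()
  k <- 0
  for (tm in seq_len(config$n_teams)) {
    team <- sprintf("Team_%02d", tm)
    for (r in seq_len(config$per_team)) {
      if (dup && tm == 2 && r == 1) {
        src <- rows[[1]]  # team 1's rank-1 compound, rewritten
        smiles <- alt_smiles_form(src$smiles)
        cid <- paste0(src$compound_id, "b")
      } else {
        k <- k + 1
        smiles <- pick$smiles[k]
        cid <- pick$id[k]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        team = team, problem = config$problem, rank = r,
        compound_id = cid, smiles = smiles,
        vendor = sprintf("SynthVendor-%d", 1 + (tm + r) %% 4),
        vendor_id = sprintf("SV-%05d", 1000 + 37 * tm + r),
        rationale = sprintf(
          "Synthetic rationale: predicted multi-target profile (team %d).",
          tm))
    }
  }
  subs <- submission_set(do.call(rbind, rows))
  if (!is.null(dir)) write_submissions(subs, dir)
  subs
}

#' Generate a synthetic reference-active set for the novelty check
#'
#' Drawn from one scaffold family (the first family present in the library),
#' so candidates from that family fail the novelty criterion (max Tc >= 0.4
#' against the reference) and candidates from other families pass.
#'
#' @param library data frame from [generate_library()].
#' @param config a `generator_config`.
#' @return list with `smiles` (character), `family`, and `fps` (list of
#'   ECFP6 `chem_fp` ready for [aux_evidence()]).
#' @export
generate_reference_actives <- function(library,
                                       config = generator_config()) {
  rng <- local_rng(stream_seed(config$seed, "reference"))
  on.exit(rng())
  fam <- library$family[1]
  members <- library$smiles[library$family == fam]
  n <- min(config$n_ref, length(members))
  smiles <- sample(members, n)
  list(smiles = smiles, family = fam,
       fps = fingerprint_set(as.list(smiles), "ecfp6_2048"))
}

#' Generate a complete synthetic challenge instance
#'
#' Library, Kd panel with planted roles, submissions (team 1's rank-1
#' compound is the planted ideal binder, team 3's the near-miss) and
#' reference actives, all deterministic under the config seed.
#'
#' @param config a `generator_config`.
#' @param dir optional directory; when given, the library (.smi), Kd panel
#'   (CSV with censoring tokens), per-team submission YAMLs and
#'   reference-active .smi file are written there.
#' @return list with `library`, `panel`, `roles`, `submissions`,
#'   `reference`, `rubric`, `config`.
#' @export
generate_challenge <- function(config = generator_config(), dir = NULL) {
  rubric <- challenge_rubric(config$problem)
  library <- generate_library(config)
  subs <- generate_submissions(library, config)
  # plant roles on submitted rank-1 compounds: team 1 ideal, team 3 near-miss
  top <- subs$entries[subs$entries$rank == 1, ]
  roles <- stats::setNames(rep("background", nrow(library)), library$id)
  ideal_id <- top$compound_id[top$team == "Team_01"]
  nm_team <- if (config$n_teams >= 3) "Team_03" else top$team[nrow(top)]
  near_id <- top$compound_id[top$team == nm_team]
  roles[ideal_id] <- "ideal"
  roles[near_id] <- "near_miss"
  pan <- generate_kd_panel(library, rubric, config, roles = roles)
  ref <- generate_reference_actives(library, config)
  inst <- list(library = library, panel = pan$panel, roles = pan$roles,
               submissions = subs, reference = ref, rubric = rubric,
               config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(paste(library$smiles, library$id),
               file.path(dir, "library.smi"))
    write_kd_table(pan$panel, file.path(dir, "kd_panel.csv"))
    write_submissions(subs, file.path(dir, "submissions"))
    writeLines(ref$smiles, file.path(dir, "reference_actives.smi"))
  }
  inst
}
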