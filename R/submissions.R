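# Challenge submission sets: the YAML prediction template (one file per
# team: up to five ranked compounds per problem, each with name, vendor and
# rationale) and its reader/writer.

SUBMISSION_MAX_RANK <- 5L

#' Construct a submission set
#'
#' @param entries data frame with columns `team`, `problem`, `rank`,
#'   `compound_id`, `smiles`, `vendor`, `vendor_id`, `rationale`.
#' @return a `submission_set`.
#' @export
submission_set <- function(entries) {
  needed <- c("team", "problem", "rank", "compound_id", "smiles",
              "vendor", "vendor_id", "rationale")
  missing_c <- setdiff(needed, colnames(entries))
  if (length(missing_c) > 0)
    stop("submission entries lack column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  errs <- character()
  for (tm in unique(entries$team)) {
    for (pb in unique(entries$problem[entries$team == tm])) {
      sub <- entries[entries$team == tm & entries$problem == pb, ]
      if (anyDuplicated(sub$rank))
        errs <- c(errs, sprintf("team %s problem %s: duplicate ranks", tm, pb))
      if (nrow(sub) > SUBMISSION_MAX_RANK)
        errs <- c(errs, sprintf(
          "team %s problem %s: %d compounds (template allows %d)",
          tm, pb, nrow(sub), SUBMISSION_MAX_RANK))
    }
  }
  if (length(errs) > 0)
    stop("invalid submission set:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(list(entries = entries), class = "submission_set")
}

#' @export
print.submission_set <- function(x, ...) {
  cat(sprintf("<submission_set> %d teams, %d entries\n",
              length(unique(x$entries$team)), nrow(x$entries)))
  invisible(x)
}

#' Read team submissions from YAML
#'
#' Each file follows the challenge template: `team`, `problem`,
#' `predictions` (list of `rank`, `compound_name`, `smiles`, `vendor`,
#' `vendor_id`, `rationale`). All schema violations across all files are
#' collected and reported together; every SMILES must parse.
#'
#' @param paths YAML file path(s), or a directory containing `.yaml` files.
#' @return a `submission_set`.
#' @export
read_submissions <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.ya?ml$", full.names = TRUE)
  if (length(paths) == 0) stop("no submission files found", call. = FALSE)
  errs <- character()
  rows <- list()
  for (p in paths) {
    y <- tryCatch(yaml::read_yaml(p), error = function(e) {
      errs <<- c(errs, sprintf("%s: YAML parse error (%s)", p,
                               conditionMessage(e)))
      NULL
    })
    if (is.null(y)) next
    for (f in c("team", "problem", "predictions"))
      if (is.null(y[[f]]))
        errs <- c(errs, sprintf("%s: missing field '%s'", p, f))
    if (is.null(y$predictions)) next
    for (k in seq_along(y$predictions)) {
      pr <- y$predictions[[k]]
      for (f in c("rank", "compound_name", "smiles", "vendor", "vendor_id"))
        if (is.null(pr[[f]]))
          errs <- c(errs, sprintf("%s: prediction %d missing field '%s'",
                                  p, k, f))
      if (!is.null(pr$smiles)) {
        ok <- tryCatch({ parse_smiles(pr$smiles); TRUE },
                       error = function(e) {
                         errs <<- c(errs, sprintf(
                           "%s (team %s): unparseable SMILES \"%s\": %s",
                           p, y$team, pr$smiles, conditionMessage(e)))
                         FALSE
                       })
        if (!ok) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        team = y$team, problem = y$problem,
        rank = as.integer(pr$rank %||% NA),
        compound_id = pr$compound_name %||% NA_character_,
        smiles = pr$smiles %||% NA_character_,
        vendor = pr$vendor %||% NA_character_,
        vendor_id = pr$vendor_id %||% NA_character_,
        rationale = pr$rationale %||% "")
    }
  }
  if (length(errs) > 0)
    stop("submission validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  submission_set(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a submission set as per-team YAML files
#'
#' @param submissions a `submission_set`.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_submissions <- function(submissions, dir) {
  stopifnot(inherits(submissions, "submission_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- submissions$entries
  files <- character()
  for (tm in unique(entries$team)) {
    sub <- entries[entries$team == tm, , drop = FALSE]
    doc <- list(
      team = tm, problem = unique(sub$problem)[1],
      predictions = lapply(seq_len(nrow(sub)), function(i) list(
        rank = sub$rank[i], compound_name = sub$compound_id[i],
        smiles = sub$smiles[i], vendor = sub$vendor[i],
        vendor_id = sub$vendor_id[i], rationale = sub$rationale[i])))
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", tm), ".yaml"))
    yaml::write_yaml(doc, f)
    files <- c(files, f)
  }
  invisible(files)
}
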