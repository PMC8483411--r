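# Kd selectivity panels: compound x kinase dissociation constants in nM with
# censoring flags ("no hit up to the assay ceiling", written as ">30000" in
# the CSV dialect).

#' Construct a Kd panel
#'
#' @param kd_nM numeric matrix (compounds x kinases) of dissociation
#'   constants in nM; censored cells carry the censoring bound.
#' @param censored logical matrix of the same shape; TRUE marks measurements
#'   above the detection limit.
#' @param censor_bound_nM the detection ceiling (default 30000 nM = 30 uM).
#' @return a `kd_panel` object.
#' @export
kd_panel <- function(kd_nM, censored = NULL, censor_bound_nM = 30000) {
  kd_nM <- as.matrix(kd_nM)
  if (is.null(censored)) censored <- matrix(FALSE, nrow(kd_nM), ncol(kd_nM),
                                            dimnames = dimnames(kd_nM))
  censored <- as.matrix(censored)
  stopifnot(identical(dim(kd_nM), dim(censored)))
  if (is.null(rownames(kd_nM)) || is.null(colnames(kd_nM)))
    stop("kd_nM needs compound rownames and kinase colnames", call. = FALSE)
  bad <- !censored & (!is.finite(kd_nM) | kd_nM <= 0)
  if (any(bad))
    stop("non-positive or missing Kd for uncensored cells: ",
         paste(head(which(bad)), collapse = ", "), call. = FALSE)
  kd_nM[censored] <- censor_bound_nM
  structure(list(kd_nM = kd_nM, censored = censored,
                 censor_bound_nM = censor_bound_nM),
            class = "kd_panel")
}

#' @export
print.kd_panel <- function(x, ...) {
  cat(sprintf("<kd_panel> %d compounds x %d kinases (%.0f%% censored)\n",
              nrow(x$kd_nM), ncol(x$kd_nM), 100 * mean(x$censored)))
  invisible(x)
}

#' Read a Kd panel from CSV
#'
#' Expected layout: first column compound identifiers, remaining columns one
#' kinase each. Cells are either a positive Kd in nM or the censoring token
#' (default `">30000"`, configurable as `">N"`).
#'
#' @param path CSV file.
#' @param censor_token literal token marking above-detection-limit cells.
#' @return a `kd_panel`.
#' @export
read_kd_table <- function(path, censor_token = ">30000") {
  if (!file.exists(path)) stop("Kd table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("Kd table needs a compound column plus kinases",
                         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate compound row(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bound <- as.numeric(sub("^>", "", censor_token))
  kin <- colnames(df)[-1]
  kd <- matrix(NA_real_, length(ids), length(kin),
               dimnames = list(ids, kin))
  cen <- matrix(FALSE, length(ids), length(kin),
                dimnames = list(ids, kin))
  for (j in seq_along(kin)) {
    cells <- trimws(df[[j + 1]])
    is_cen <- cells == censor_token
    vals <- suppressWarnings(as.numeric(cells))
    bad <- !is_cen & is.na(vals)
    if (any(bad))
      stop(sprintf("unrecognized Kd cell \"%s\" (compound %s, kinase %s)",
                   cells[which(bad)[1]], ids[which(bad)[1]], kin[j]),
           call. = FALSE)
    kd[, j] <- ifelse(is_cen, bound, vals)
    cen[, j] <- is_cen
  }
  kd_panel(kd, cen, censor_bound_nM = bound)
}

#' Write a Kd panel to CSV with censoring tokens
#'
#' @param panel a `kd_panel`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_kd_table <- function(panel, path) {
  stopifnot(inherits(panel, "kd_panel"))
  mat <- matrix(format_kd_cell(panel$kd_nM, panel$censored,
                               panel$censor_bound_nM),
                nrow(panel$kd_nM), dimnames = dimnames(panel$kd_nM))
  df <- data.frame(compound = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_kd_cell <- function(kd, cen, bound) {
  ifelse(cen, paste0(">", format(bound, scientific = FALSE, trim = TRUE)),
         format(kd, scientific = FALSE, trim = TRUE, digits = 6))
}
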