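# Trial data container: per-individual treatment group, one self-report Q,
# and K >= 2 biomarker replicate columns that are non-missing only for
# calibration sub-study members.

new_trial_dataset <- function(group, q, m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  colnames(m) <- paste0("m", seq_len(ncol(m)))
  structure(
    list(group = as.integer(group),
         q = as.numeric(q),
         m = m,
         in_substudy = rowSums(!is.na(m)) >= 2L),
    class = "trial_dataset")
}

#' Construct a calibration-trial dataset
#'
#' Bundles the per-individual data of a two-arm trial with a biomarker
#' calibration sub-study: treatment group (1 = control, 2 = intervention),
#' one self-report measurement `q` per individual, and `K >= 2` biomarker
#' replicate columns that are non-missing only for sub-study members.
#' Sub-study membership is derived from the missingness pattern: an
#' individual is in the sub-study iff at least two replicates are observed.
#'
#' @param group integer vector of treatment labels, 1 (control) or
#'   2 (intervention).
#' @param q numeric vector of self-report measurements on the analysis
#'   scale; must be non-missing for every individual.
#' @param m numeric matrix (or data frame) of biomarker replicates, one
#'   column per replicate; rows for individuals outside the sub-study must
#'   be entirely `NA`.
#'
#' @return An object of class `trial_dataset`: a list with elements
#'   `group`, `q`, `m` and the derived logical `in_substudy`.
#' @seealso [read_trial_csv()], [validate_dataset()]
#' @export
#' @examples
#' d <- trial_dataset(group = rep(1:2, each = 3),
#'                    q = c(4.1, 4.5, 4.4, 3.9, 4.0, 3.7),
#'                    m = cbind(c(4.2, 4.6, 4.3, 3.8, 4.1, 3.6),
#'                              c(4.0, 4.7, 4.5, 3.7, 3.9, 3.8)))
#' d
trial_dataset <- function(group, q, m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m)) stop("`m` must be a matrix of biomarker replicates")
  if (ncol(m) < 2L) stop("at least two biomarker replicate columns are required")
  n <- length(q)
  if (length(group) != n || nrow(m) != n)
    stop("`group`, `q` and `m` must have one entry per individual")
  d <- new_trial_dataset(group, q, m)
  v <- validate_dataset(d)
  if (length(v))
    stop("invalid trial dataset:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  d
}

#' Validate a trial dataset
#'
#' Checks the structural invariants of a [trial_dataset()] and reports every
#' violation found; never throws.  The invariants are: all group labels in
#' \{1, 2\}; `q` non-missing everywhere; each individual has either no
#' observed biomarker replicates or at least two (no partial rows); and each
#' group contains at least two members and at least two sub-study members
#' (estimability).
#'
#' @param d a `trial_dataset` (or a bare list with the same fields).
#' @return Character vector of violation descriptions; empty iff the
#'   dataset is valid.
#' @export
validate_dataset <- function(d) {
  out <- character(0)
  bad_grp <- setdiff(unique(d$group), c(1L, 2L))
  if (length(bad_grp))
    out <- c(out, paste0("group labels outside {1,2}: ",
                         paste(bad_grp, collapse = ", ")))
  if (anyNA(d$group))
    out <- c(out, "missing group labels")
  if (anyNA(d$q))
    out <- c(out, paste0("missing self-report q in rows: ",
                         paste(which(is.na(d$q)), collapse = ", ")))
  nobs <- rowSums(!is.na(d$m))
  partial <- which(nobs == 1L)
  if (length(partial))
    out <- c(out, paste0("rows with a single biomarker replicate ",
                         "(need none or >= 2): ",
                         paste(partial, collapse = ", ")))
  for (i in 1:2) {
    gi <- d$group == i & !is.na(d$group)
    if (sum(gi) < 2L)
      out <- c(out, paste0("group ", i, " has fewer than 2 members"))
    if (sum(gi & d$in_substudy) < 2L)
      out <- c(out, paste0("group ", i,
                           " has fewer than 2 calibration sub-study members"))
  }
  out
}

#' Read a calibration-trial dataset from CSV
#'
#' Expects a header `group,q,m1,m2[,...mK]`, one row per individual, with
#' missing biomarker cells encoded as empty fields or the literal `NA`.
#' Sub-study membership is derived from the biomarker missingness pattern.
#'
#' @param path path to the CSV file.
#' @param k number of replicate columns to read (`m1..mk`); by default all
#'   columns named `m1`, `m2`, ... present in the file are used.
#' @return A validated [trial_dataset()].
#' @seealso [write_trial_csv()]
#' @export
read_trial_csv <- function(path, k = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  if (!all(c("group", "q") %in% names(df)))
    stop("malformed file: columns `group` and `q` are required")
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  if (!is.null(k)) {
    want <- paste0("m", seq_len(k))
    if (!all(want %in% mcols))
      stop("malformed file: replicate columns ",
           paste(setdiff(want, mcols), collapse = ", "), " not found")
    mcols <- want
  }
  if (length(mcols) < 2L)
    stop("malformed file: need at least columns m1 and m2")
  if (!all(vapply(df[c("group", "q", mcols)], is.numeric, logical(1))))
    stop("malformed file: non-numeric values in group/q/m columns")
  trial_dataset(df$group, df$q, as.matrix(df[mcols]))
}

#' Write a calibration-trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]: writes `group,q,m1..mK` with missing
#' biomarker cells as empty fields.  Values are written with 17 significant
#' digits so that a read/write/read cycle reproduces the dataset exactly.
#'
#' @param d a [trial_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(d, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  df <- data.frame(group = d$group, q = fmt(d$q))
  for (j in seq_len(ncol(d$m))) df[[colnames(d$m)[j]]] <- fmt(d$m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- tabulate(x$group, nbins = 2L)
  ns <- vapply(1:2, function(i) sum(x$in_substudy[x$group == i]), integer(1))
  cat("Calibration-trial dataset: ", length(x$q), " individuals, ",
      ncol(x$m), " biomarker replicate columns\n", sep = "")
  cat(sprintf("  group 1 (control):      N = %d, sub-study n = %d\n",
              n[1], ns[1]))
  cat(sprintf("  group 2 (intervention): N = %d, sub-study n = %d\n",
              n[2], ns[2]))
  invisible(x)
}

# Per-group totals and sub-study sizes, as used throughout.
group_sizes <- function(d) {
  list(N = tabulate(d$group, nbins = 2L),
       n = vapply(1:2, function(i) sum(d$in_substudy[d$group == i]),
                  integer(1)))
}
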