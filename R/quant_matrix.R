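#' Label-free quantification matrix
#'
#' Container for a proteins-by-samples intensity table from a
#' co-immunoprecipitation / mass-spectrometry experiment. Rows are proteins,
#' columns are samples; a zero (or missing) intensity means the protein was
#' not detected in that sample. Each sample belongs to a group: the bait
#' pull-down, one or more comparator pull-downs used to subtract generic
#' interactors, and an untagged negative control.
#'
#' @param values Numeric matrix (proteins x samples) of nonnegative LFQ
#'   intensities. `NA` is recoded to 0 ("not detected"). Row names are used
#'   as protein identifiers if `protein_ids` is not given.
#' @param groups Character vector, one group label per column (e.g. "bait",
#'   "comparatorA", "comparatorB", "negative").
#' @param replicates Optional integer vector of replicate indices per column;
#'   defaults to 1..k within each group.
#' @param protein_ids Optional character vector of unique protein ids.
#' @return An object of class `quant_matrix`: a list with elements `values`,
#'   `groups`, `replicates`, `protein_ids`.
#' @examples
#' m <- matrix(abs(rnorm(24, 20, 5)), nrow = 2)
#' qm <- quant_matrix(m, groups = rep(c("bait", "A", "B", "neg"), each = 3))
#' qm
#' @export
quant_matrix <- function(values, groups, replicates = NULL,
                         protein_ids = rownames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  values[is.na(values)] <- 0
  if (any(values < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (length(groups) != ncol(values)) {
    stop("`groups` must have one label per column", call. = FALSE)
  }
  groups <- as.character(groups)
  if (is.null(protein_ids)) protein_ids <- paste0("P", seq_len(nrow(values)))
  protein_ids <- as.character(protein_ids)
  if (anyDuplicated(protein_ids)) {
    stop("protein ids must be unique", call. = FALSE)
  }
  if (length(protein_ids) != nrow(values)) {
    stop("`protein_ids` must have one id per row", call. = FALSE)
  }
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  }
  rownames(values) <- protein_ids
  colnames(values) <- paste0(groups, "_", replicates)
  structure(
    list(values = values, groups = groups,
         replicates = as.integer(replicates), protein_ids = protein_ids),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("quant_matrix: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("zeros (not detected): %d (%.1f%%)\n",
              sum(x$values == 0), 100 * mean(x$values == 0)))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Subset the rows of a quantification matrix
#'
#' @param x A `quant_matrix`.
#' @param i Row index (logical, integer or protein ids).
#' @param ... Ignored.
#' @return A `quant_matrix` with the selected proteins, column metadata
#'   unchanged.
#' @export
`[.quant_matrix` <- function(x, i, ...) {
  quant_matrix(x$values[i, , drop = FALSE], groups = x$groups,
               replicates = x$replicates,
               protein_ids = x$protein_ids[
                 if (is.character(i)) match(i, x$protein_ids) else i])
}

group_columns <- function(qm, group) {
  idx <- which(qm$groups == group)
  if (length(idx) == 0L) {
    stop(sprintf("group '%s' has no samples", group), call. = FALSE)
  }
  idx
}

#' Read a quantification matrix from CSV
#'
#' Expects a header row; the first column holds protein identifiers, the
#' remaining columns intensities. Group membership comes either from a
#' sidecar JSON file mapping column names to `{"group": ..., "replicate": ...}`
#' or from column names of the form `group_replicate` (e.g. `bait_1`).
#' Empty cells, `NA` and 0 all mean "not detected".
#'
#' @param path CSV path.
#' @param groups_json Optional path to the sidecar JSON.
#' @return A [quant_matrix()].
#' @export
read_quant_matrix <- function(path, groups_json = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[is.na(vals)] <- 0
  cn <- colnames(vals)
  if (!is.null(groups_json)) {
    mp <- jsonlite::read_json(groups_json, simplifyVector = FALSE)
    missing_cols <- setdiff(cn, names(mp))
    if (length(missing_cols)) {
      stop("columns missing from groups file: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    groups <- vapply(cn, function(s) as.character(mp[[s]]$group), "")
    reps <- vapply(cn, function(s) as.integer(mp[[s]]$replicate), 1L)
  } else {
    groups <- sub("_[^_]*$", "", cn)
    reps <- suppressWarnings(as.integer(sub("^.*_", "", cn)))
    if (anyNA(reps)) {
      stop("column names are not of the form group_replicate; ",
           "supply `groups_json`", call. = FALSE)
    }
  }
  quant_matrix(vals, groups = groups, replicates = reps, protein_ids = ids)
}

#' Write a quantification matrix to CSV (with optional sidecar JSON)
#'
#' @param qm A `quant_matrix`.
#' @param path Output CSV path.
#' @param groups_json Optional path for the column-to-group JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(qm, path, groups_json = NULL) {
  df <- data.frame(protein_id = qm$protein_ids, qm$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(groups_json)) {
    mp <- stats::setNames(
      lapply(seq_along(qm$groups), function(j) {
        list(group = qm$groups[j], replicate = qm$replicates[j])
      }),
      colnames(qm$values)
    )
    jsonlite::write_json(mp, groups_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
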