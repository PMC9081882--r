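#' Construct a cohort density table
#'
#' A cohort is the unit of network inference: one experimental condition,
#' one row per animal, one column per atlas region, entries in c-Fos+
#' cells/mm^2.  Missing cells are allowed (`NA`) and handled downstream by
#' pairwise-complete deletion.
#'
#' @param densities Numeric matrix, animals x regions; column names must
#'   equal the atlas region codes (same order).
#' @param condition Single condition label.
#' @param animals Optional animal IDs (defaults to rownames or `a1..an`).
#' @param atlas A `fos_atlas`; defaults to [default_atlas()].
#' @return An object of class `fos_cohort` with fields `condition`,
#'   `animals`, `densities` and `atlas`.
#' @export
cohort_table <- function(densities, condition, animals = NULL,
                         atlas = default_atlas()) {
  densities <- as.matrix(densities)
  storage.mode(densities) <- "double"
  if (is.null(animals)) {
    animals <- rownames(densities)
    if (is.null(animals)) animals <- paste0("a", seq_len(nrow(densities)))
  }
  if (length(animals) != nrow(densities))
    stop("length of animals must match number of density rows")
  if (anyDuplicated(animals))
    stop("duplicate animal IDs: ",
         paste(unique(animals[duplicated(animals)]), collapse = ", "))
  if (is.null(colnames(densities)))
    stop("density matrix must carry region codes as column names")
  unknown <- setdiff(colnames(densities), atlas$code)
  if (length(unknown))
    stop("unknown region column(s) not in atlas: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(atlas$code, colnames(densities))
  if (length(absent))
    stop("atlas region(s) missing from table: ",
         paste(absent, collapse = ", "))
  densities <- densities[, atlas$code, drop = FALSE]
  if (any(densities < 0, na.rm = TRUE))
    stop("densities must be non-negative (cells/mm^2)")
  rownames(densities) <- animals
  structure(
    list(condition = as.character(condition)[1], animals = as.character(animals),
         densities = densities, atlas = atlas),
    class = "fos_cohort")
}

#' Read a cohort density table from delimited text
#'
#' Expects a header `animal_id,condition,<region codes...>` with one row per
#' animal and an `NA` token for missing densities.  The region columns are
#' validated against the atlas; unknown or missing columns are an error.
#' Comma- and tab-separated files are auto-detected from the extension
#' (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path Path to a CSV/TSV file.
#' @param atlas A `fos_atlas`; defaults to [default_atlas()].
#' @return A `fos_cohort`.
#' @seealso [write_cohort()] for the loss-free inverse.
#' @export
read_cohort <- function(path, atlas = default_atlas()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("animal_id", "condition") %in% names(df)))
    stop("cohort file must have 'animal_id' and 'condition' columns: ", path)
  region_cols <- setdiff(names(df), c("animal_id", "condition"))
  unknown <- setdiff(region_cols, atlas$code)
  if (length(unknown))
    stop("cohort file has column(s) not in atlas: ",
         paste(unknown, collapse = ", "))
  dens <- df[, region_cols, drop = FALSE]
  non_num <- names(dens)[!vapply(dens, is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric density column(s): ", paste(non_num, collapse = ", "))
  cond <- unique(df$condition)
  if (length(cond) != 1L)
    stop("cohort file mixes conditions: ", paste(cond, collapse = ", "))
  cohort_table(as.matrix(dens), condition = cond,
               animals = as.character(df$animal_id), atlas = atlas)
}

#' Write a cohort density table to delimited text
#'
#' Inverse of [read_cohort()]: full-precision, loss-free round trip with
#' explicit `NA` tokens for missing cells.
#'
#' @param cohort A `fos_cohort`.
#' @param path Output path (`.tsv`/`.txt` writes tabs, otherwise commas).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fos_cohort"))
  if (nrow(cohort$densities) == 0L)
    stop("refusing to write an empty cohort (0 animals)")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(animal_id = cohort$animals,
                   condition = cohort$condition,
                   cohort$densities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @export
print.fos_cohort <- function(x, ...) {
  cat("c-Fos cohort '", x$condition, "': ", length(x$animals), " animals x ",
      ncol(x$densities), " regions", sep = "")
  n_na <- sum(is.na(x$densities))
  if (n_na) cat(" (", n_na, " missing cells)", sep = "")
  cat("\n")
  invisible(x)
}
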