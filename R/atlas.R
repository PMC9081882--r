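#' The default 30-region lateralized brain atlas
#'
#' Fifteen brain regions per hemisphere, ordered frontal to caudal with
#' left/right pairs adjacent.  Region codes are `"<Name>-<L|R>"`; left is
#' ipsilateral to the stimulation site.  Each region carries two groupings:
#' `display_group` (cortical, hippocampal, amygdalar, thalamic, brainstem),
#' used for plotting, and `area_group` (frontal, hippocampal, amygdalar,
#' brainstem, other), used for hemispheric edge-count summaries.  PVT, RSP
#' and pRSP belong to `area_group` "other": they take part in every network
#' computation but are not tabulated as a named area group.
#'
#' @return An object of class `fos_atlas`: a data frame with columns
#'   `code`, `name`, `hemisphere`, `display_group`, `area_group`,
#'   `bregma_from`, `bregma_to` and one row per lateralized region (30 rows).
#' @examples
#' atlas <- default_atlas()
#' nrow(atlas)                      # 30
#' table(atlas$hemisphere)          # 15 left, 15 right
#' @export
default_atlas <- function() {
  base <- data.frame(
    name = c("Cg", "PrL", "IL", "DG", "CA1", "CA3", "BLA", "LA", "CeA",
             "PVT", "RSP", "pRSP", "LC", "NTS", "DMX"),
    full_name = c(
      "cingulate cortex", "prelimbic cortex", "infralimbic cortex",
      "dentate gyrus", "hippocampal CA1", "hippocampal CA3",
      "basolateral amygdala", "lateral amygdala", "central amygdala",
      "paraventricular nucleus of the thalamus",
      "anterior retrosplenial cortex", "posterior retrosplenial cortex",
      "locus coeruleus", "nucleus of the solitary tract",
      "dorsal vagal nucleus"),
    display_group = c("cortical", "cortical", "cortical",
                      "hippocampal", "hippocampal", "hippocampal",
                      "amygdalar", "amygdalar", "amygdalar",
                      "thalamic", "cortical", "cortical",
                      "brainstem", "brainstem", "brainstem"),
    area_group = c("frontal", "frontal", "frontal",
                   "hippocampal", "hippocampal", "hippocampal",
                   "amygdalar", "amygdalar", "amygdalar",
                   "other", "other", "other",
                   "brainstem", "brainstem", "brainstem"),
    bregma_from = c(1.94, 1.94, 1.94, -1.46, -1.46, -1.46, -1.46, -1.46,
                    -1.46, -1.46, -1.46, -1.46, -5.34, -7.32, -7.32),
    bregma_to = c(1.54, 1.54, 1.54, -1.82, -1.82, -1.82, -1.82, -1.82,
                  -1.82, -1.82, -2.92, -2.92, -5.68, -7.64, -7.64),
    stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(base)), each = 2L)
  hemi <- rep(c("left", "right"), times = nrow(base))
  atlas <- data.frame(
    code = paste0(base$name[idx], "-", ifelse(hemi == "left", "L", "R")),
    name = base$full_name[idx],
    hemisphere = hemi,
    display_group = base$display_group[idx],
    area_group = base$area_group[idx],
    bregma_from = base$bregma_from[idx],
    bregma_to = base$bregma_to[idx],
    stringsAsFactors = FALSE)
  validate_atlas(atlas)
}

#' Read a region atlas from a YAML or JSON file
#'
#' The file must contain a list of regions, each with at least `code`,
#' `hemisphere`, `display_group` and `area_group` fields (plus optional
#' `name`, `bregma_from`, `bregma_to`).  Used to override the built-in
#' [default_atlas()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` atlas file.
#' @return A `fos_atlas` data frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.data.frame(raw)) {
    atlas <- raw
  } else {
    atlas <- do.call(rbind, lapply(raw, function(r) {
      data.frame(
        code = r$code,
        name = if (is.null(r$name)) r$code else r$name,
        hemisphere = r$hemisphere,
        display_group = r$display_group,
        area_group = r$area_group,
        bregma_from = if (is.null(r$bregma_from)) NA_real_ else r$bregma_from,
        bregma_to = if (is.null(r$bregma_to)) NA_real_ else r$bregma_to,
        stringsAsFactors = FALSE)
    }))
  }
  validate_atlas(atlas, require_default_size = FALSE)
}

#' Validate a region atlas
#'
#' Checks the atlas invariants (required columns, unique codes, known
#' hemisphere and area-group labels) and stamps the `fos_atlas` class.
#' Default-style atlases must additionally have 30 regions split 15/15
#' across hemispheres.
#'
#' @param atlas Data frame of regions.
#' @param require_default_size Enforce the 30-region, 15-per-hemisphere
#'   shape (default `TRUE`).
#' @return The validated `fos_atlas`.
#' @export
validate_atlas <- function(atlas, require_default_size = TRUE) {
  stopifnot(is.data.frame(atlas))
  needed <- c("code", "hemisphere", "display_group", "area_group")
  missing_cols <- setdiff(needed, names(atlas))
  if (length(missing_cols))
    stop("atlas lacks required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atlas$code))
    stop("duplicate region codes in atlas: ",
         paste(unique(atlas$code[duplicated(atlas$code)]), collapse = ", "))
  bad_hemi <- setdiff(unique(atlas$hemisphere), c("left", "right"))
  if (length(bad_hemi))
    stop("hemisphere must be 'left' or 'right'; found: ",
         paste(bad_hemi, collapse = ", "))
  bad_grp <- setdiff(unique(atlas$area_group),
                     c("frontal", "hippocampal", "amygdalar", "brainstem", "other"))
  if (length(bad_grp))
    stop("unknown area_group value(s): ", paste(bad_grp, collapse = ", "))
  if (require_default_size) {
    if (nrow(atlas) != 30L)
      stop("default-style atlas must have 30 regions, got ", nrow(atlas))
    if (sum(atlas$hemisphere == "left") != 15L)
      stop("default-style atlas must have 15 regions per hemisphere")
  }
  class(atlas) <- c("fos_atlas", "data.frame")
  atlas
}

#' Regional c-Fos density from repeated cell counts
#'
#' Density is the mean c-Fos-positive cell count over repeated
#' determinations of the same region, divided by the area of one
#' determination.
#'
#' @param counts Non-negative cell counts, one per determination.
#' @param area Area of a single determination in mm^2 (scalar, > 0).
#' @return Density in c-Fos+ cells/mm^2.
#' @examples
#' compute_density(c(4, 6, 8, 2), area = 0.5)  # 10
#' @export
compute_density <- function(counts, area) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative numbers")
  if (!is.numeric(area) || length(area) != 1L || is.na(area) || area <= 0)
    stop("area must be a single positive number (mm^2)")
  mean(counts) / area
}

#' @export
print.fos_atlas <- function(x, ...) {
  cat("Lateralized region atlas: ", nrow(x), " regions (",
      sum(x$hemisphere == "left"), " left / ",
      sum(x$hemisphere == "right"), " right)\n", sep = "")
  cat("Area groups:",
      paste(sprintf("%s=%d", names(table(x$area_group)), table(x$area_group)),
            collapse = ", "), "\n")
  invisible(x)
}
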