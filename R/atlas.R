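#' The bundled AAL-90 atlas table
#'
#' Returns the 90-region Automated Anatomical Labeling parcellation of the
#' cerebrum used throughout the package: numeric labels 1..90, full region
#' names, short abbreviations and hemisphere. Odd labels are left-hemisphere,
#' even labels right (e.g. thalamus L = 77, R = 78). MNI centroid
#' coordinates are not bundled; supply them via `read_atlas()` from your own
#' table if you need BrainNet Viewer export.
#'
#' @return a data.frame with columns `label`, `name`, `abbreviation`,
#'   `hemisphere` and 90 rows.
#' @export
#' @examples
#' atlas <- aal90_atlas()
#' atlas[atlas$label %in% c(77, 78), ]
aal90_atlas <- function() {
  path <- system.file("extdata", "aal90_atlas.tsv", package = "dysconn",
                      mustWork = TRUE)
  read_atlas(path)
}

#' Read an atlas label table
#'
#' The table must be tab-separated with columns `label` (integers 1..N,
#' unique and contiguous), `name`, `abbreviation` and `hemisphere` (L/R);
#' optional columns `mni_x`, `mni_y`, `mni_z` carry region centroid
#' coordinates in millimetres.
#'
#' @param path path to a TSV file.
#' @return a validated data.frame ordered by label.
#' @export
read_atlas <- function(path) {
  assert_that(file.exists(path), paste0("atlas file not found: ", path))
  at <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("label", "name", "abbreviation", "hemisphere")
  missing <- setdiff(required, names(at))
  assert_that(length(missing) == 0,
              paste0("atlas table lacks column(s): ",
                     paste(missing, collapse = ", ")))
  at <- at[order(at$label), , drop = FALSE]
  assert_that(!anyDuplicated(at$label), "atlas labels must be unique")
  assert_that(identical(as.integer(at$label), seq_len(nrow(at))),
              "atlas labels must be contiguous integers starting at 1")
  assert_that(all(at$hemisphere %in% c("L", "R")),
              "atlas hemisphere must be 'L' or 'R'")
  assert_that(!anyDuplicated(at$abbreviation),
              "atlas abbreviations must be unique")
  rownames(at) <- NULL
  at
}

# region labels used for a simulated cohort: AAL abbreviations when the
# region count matches the atlas, generic zero-padded labels otherwise
default_region_labels <- function(n_regions) {
  if (n_regions == 90L) return(aal90_atlas()$abbreviation)
  sprintf("R%03d", seq_len(n_regions))
}
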