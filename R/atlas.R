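#' Load a node (region) label table
#'
#' Reads a tab-separated atlas label table with columns `index`, `name`,
#' `abbreviation`, `class` (cortical/subcortical) and `dmn` (0/1 flag for
#' default-mode-network membership). The packaged default is the 90-region
#' automated-anatomical-labelling parcellation (78 cortical + 12 subcortical
#' regions), with the seven default-mode nodes used by the synthetic
#' generator flagged: bilateral medial superior frontal gyrus, left
#' posterior cingulate gyrus, left angular gyrus, right precuneus, right
#' amygdala, right hippocampus.
#'
#' @param path path to a label TSV; `NULL` loads the packaged 90-region
#'   table.
#' @param n_regions expected number of rows; an error is raised on mismatch
#'   so a config/atlas disagreement cannot pass silently.
#' @return a data.frame with 90 (or `n_regions`) rows.
#' @examples
#' atlas <- load_atlas_labels()
#' table(atlas$class)
#' atlas$abbreviation[atlas$dmn == 1]
#' @export
load_atlas_labels <- function(path = NULL, n_regions = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal90_labels.tsv", package = "connsweep")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "name", "abbreviation", "class", "dmn")
  if (!all(need %in% names(tab))) {
    stop("atlas table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$abbreviation)) {
    stop("duplicate abbreviations in atlas table: ",
         paste(unique(tab$abbreviation[duplicated(tab$abbreviation)]),
               collapse = ", "))
  }
  if (!all(tab$class %in% c("cortical", "subcortical"))) {
    stop("atlas class column must be 'cortical' or 'subcortical'")
  }
  if (!is.null(n_regions) && nrow(tab) != n_regions) {
    stop("atlas has ", nrow(tab), " regions but config expects ", n_regions)
  }
  tab
}

#' Generic label table for non-standard region counts
#'
#' Used by reduced-size (smoke-test) runs where the packaged 90-region
#' parcellation does not apply: regions are labelled R1..RN and the first
#' `min(7, n)` carry the default-mode flag, matching the synthetic
#' generator's convention at reduced sizes.
#'
#' @param n number of regions.
#' @return data.frame with the same columns as [load_atlas_labels()].
#' @export
generic_atlas <- function(n) {
  data.frame(index = seq_len(n), name = paste("region", seq_len(n)),
             abbreviation = paste0("R", seq_len(n)), class = "cortical",
             dmn = as.integer(seq_len(n) <= min(7L, n)),
             stringsAsFactors = FALSE)
}

#' Indices of the default-mode seed regions in the packaged atlas
#'
#' @return named integer vector (names are region abbreviations).
#' @export
dmn_region_indices <- function() {
  atlas <- load_atlas_labels()
  idx <- atlas$index[atlas$dmn == 1]
  names(idx) <- atlas$abbreviation[atlas$dmn == 1]
  idx
}
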