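#' AAL-90 atlas lookup table
#'
#' Region names, hemisphere, lobe assignment and left/right homolog pairing
#' for the 90-region automated anatomical labeling (AAL) parcellation
#' (78 cortical + 12 subcortical regions; cerebellum excluded). ROI indices
#' are 1-based and follow the standard AAL ordering (left/right
#' interleaved). The lobe grouping (frontal, central, parietal, occipital,
#' temporal, limbic, insula+subcortical) ships as an editable CSV in
#' `inst/extdata/aal90_atlas.csv`; pass a modified table anywhere an
#' `atlas` argument is accepted.
#'
#' @param path Path to an atlas CSV with columns `index`, `name`,
#'   `hemisphere`, `lobe`, `homolog`. Defaults to the shipped AAL-90 table.
#' @return A data.frame with one row per ROI, validated so that `homolog`
#'   is a perfect involution across hemispheres.
#' @examples
#' atlas <- aal90_atlas()
#' head(atlas)
#' @export
aal90_atlas <- function(path = system.file("extdata", "aal90_atlas.csv",
                                           package = "megfocus")) {
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
  atlas
}

validate_atlas <- function(atlas) {
  required <- c("index", "name", "hemisphere", "lobe", "homolog")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0L) {
    stop("atlas table lacks column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(atlas)
  if (!identical(as.integer(atlas$index), seq_len(n))) {
    stop("atlas `index` must be 1..", n, " in order")
  }
  hom <- as.integer(atlas$homolog)
  if (any(hom < 1L | hom > n) || !all(hom[hom] == atlas$index)) {
    stop("atlas `homolog` must be an involution over 1..", n)
  }
  if (any(atlas$hemisphere[hom] == atlas$hemisphere)) {
    stop("atlas `homolog` must pair regions across hemispheres")
  }
  invisible(atlas)
}
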