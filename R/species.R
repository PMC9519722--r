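#' Tree species groups
#'
#' The simulator distinguishes seven species groups that cover the common
#' low- to mid-elevation species mix north of the Alps: Norway spruce,
#' silver fir, Douglas-fir, other conifers, European beech, oak and other
#' broadleaves. Every demographic and allometric sub-model is parameterised
#' per group; leaf type (conifer/broadleaf) is derived from the group.
#'
#' @return Character vector of the recognised species group codes.
#' @export
#' @examples
#' species_groups()
species_groups <- function() {
  c("spruce", "fir", "douglas_fir", "other_conifer",
    "beech", "oak", "other_broadleaf")
}

#' Leaf type of a species group
#'
#' @param species_group Character vector of species group codes
#'   (see [species_groups()]).
#' @return Character vector, `"conifer"` or `"broadleaf"`.
#' @export
#' @examples
#' leaf_type(c("spruce", "oak"))
leaf_type <- function(species_group) {
  conifers <- c("spruce", "fir", "douglas_fir", "other_conifer")
  out <- ifelse(species_group %in% conifers, "conifer", "broadleaf")
  bad <- !species_group %in% species_groups()
  if (any(bad)) {
    stop("unknown species group(s): ",
         paste(unique(species_group[bad]), collapse = ", "))
  }
  out
}
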