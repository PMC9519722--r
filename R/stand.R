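#' Construct a stand object
#'
#' A stand is a one-hectare individual-tree list plus site metadata and the
#' deadwood/harvested-wood-product carbon pools carried through a simulation.
#' The tree list is a data.frame with columns `tree_id`, `species_group`,
#' `dbh` (cm), `height` (m), `status` (`live`/`dead`/`harvested`) and
#' `origin` (`initial`/`ingrowth`/`planted`).
#'
#' @param trees Tree-list data.frame (may have zero rows).
#' @param forest_type `"beech_dominated"` or `"spruce_dominated"`.
#' @param stage `"pole"` or `"mature"`.
#' @param year Calendar year of the state.
#' @param deadwood Named numeric vector of the four deadwood compartments
#'   (m3/ha): `coarse_conifer`, `fine_conifer`, `coarse_broadleaf`,
#'   `fine_broadleaf`. Defaults to zero.
#' @param hwp Named numeric vector of the four harvested-wood-product carbon
#'   pools (tC/ha): `sawn_timber`, `panels`, `paper`, `energy`. Defaults to
#'   zero.
#' @return Object of class `stand`.
#' @export
new_stand <- function(trees,
                      forest_type = c("beech_dominated", "spruce_dominated"),
                      stage = c("pole", "mature"),
                      year = 2016,
                      deadwood = NULL,
                      hwp = NULL) {
  forest_type <- match.arg(forest_type)
  stage <- match.arg(stage)
  trees <- validate_tree_list(trees)
  if (is.null(deadwood)) {
    deadwood <- c(coarse_conifer = 0, fine_conifer = 0,
                  coarse_broadleaf = 0, fine_broadleaf = 0)
  }
  if (is.null(hwp)) {
    hwp <- c(sawn_timber = 0, panels = 0, paper = 0, energy = 0)
  }
  stopifnot(all(deadwood >= 0), all(hwp >= 0))
  structure(
    list(trees = trees, forest_type = forest_type, stage = stage,
         year = year, area_ha = 1.0,
         deadwood = deadwood, hwp = hwp),
    class = "stand"
  )
}

validate_tree_list <- function(trees) {
  cols <- c("tree_id", "species_group", "dbh", "height", "status", "origin")
  if (nrow(trees) == 0 && !all(cols %in% names(trees))) {
    trees <- data.frame(tree_id = integer(), species_group = character(),
                        dbh = numeric(), height = numeric(),
                        status = character(), origin = character(),
                        stringsAsFactors = FALSE)
  }
  miss <- setdiff(cols, names(trees))
  if (length(miss) > 0) {
    stop("tree list is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(trees$tree_id)) stop("tree_id must be unique")
  if (any(trees$dbh <= 0)) stop("all dbh must be > 0")
  if (!all(trees$status %in% c("live", "dead", "harvested"))) {
    stop("status must be live, dead or harvested")
  }
  if (!all(trees$origin %in% c("initial", "ingrowth", "planted"))) {
    stop("origin must be initial, ingrowth or planted")
  }
  leaf_type(unique(trees$species_group))  # errors on unknown groups
  trees[cols]
}

live_trees <- function(stand) {
  stand$trees[stand$trees$status == "live", , drop = FALSE]
}

#' Stand-level structure metrics
#'
#' Basal area, stem number, quadratic mean diameter and growing stock of the
#' live trees in a 1-ha stand, plus the one-sided competition index BAL
#' (basal area of larger trees) per live tree.
#'
#' @param stand A `stand` object.
#' @param params Parameter list (needed for growing stock via the volume
#'   allometry); defaults to [default_params()].
#' @return `stand_metrics()`: list with `basal_area` (m2/ha), `stems`
#'   (n/ha), `qmd` (cm), `growing_stock` (m3/ha). `tree_bal()`: numeric
#'   vector of BAL (m2/ha) aligned with the live-tree rows.
#' @export
#' @examples
#' st <- example_stand()
#' stand_metrics(st)
stand_metrics <- function(stand, params = default_params()) {
  lv <- live_trees(stand)
  n <- nrow(lv)
  ba <- sum(pi * (lv$dbh / 200)^2)
  list(
    basal_area = ba,
    stems = n,
    qmd = if (n > 0) sqrt(mean(lv$dbh^2)) else 0,
    growing_stock = sum(tree_volume(lv$dbh, lv$species_group, params))
  )
}

#' @rdname stand_metrics
#' @export
tree_bal <- function(stand) {
  lv <- live_trees(stand)
  if (nrow(lv) == 0) return(numeric(0))
  g <- pi * (lv$dbh / 200)^2
  # BAL = sum of basal areas of strictly larger trees; ties share rank by
  # tree_id order so the vector is non-increasing in dbh rank.
  ord <- order(-lv$dbh, lv$tree_id)
  bal <- numeric(length(g))
  bal[ord] <- cumsum(c(0, g[ord][-length(g)]))
  bal
}

#' @export
print.stand <- function(x, ...) {
  m <- stand_metrics(x)
  cat(sprintf("<stand> %s / %s, year %d\n", x$forest_type, x$stage, x$year))
  cat(sprintf("  live trees: %d  BA: %.1f m2/ha  QMD: %.1f cm  GS: %.0f m3/ha\n",
              m$stems, m$basal_area, m$qmd, m$growing_stock))
  cat(sprintf("  deadwood: %.1f m3/ha  HWP carbon: %.1f tC/ha\n",
              sum(x$deadwood), sum(x$hwp)))
  invisible(x)
}

#' Read / write a tree list as CSV
#'
#' Plain-CSV exchange format for stand tree lists: columns `tree_id`,
#' `species_group`, `dbh_cm`, `height_m`, `origin`, `status`.
#'
#' @param stand A `stand` object.
#' @param path File path.
#' @param forest_type,stage,year Metadata to attach when reading.
#' @return `write_tree_list()` the path invisibly; `read_tree_list()` a
#'   `stand`.
#' @export
write_tree_list <- function(stand, path) {
  tr <- stand$trees
  out <- data.frame(tree_id = tr$tree_id, species_group = tr$species_group,
                    dbh_cm = tr$dbh, height_m = tr$height,
                    origin = tr$origin, status = tr$status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tree_list
#' @export
read_tree_list <- function(path, forest_type = "beech_dominated",
                           stage = "mature", year = 2016) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  trees <- data.frame(tree_id = d$tree_id, species_group = d$species_group,
                      dbh = d$dbh_cm, height = d$height_m,
                      status = d$status, origin = d$origin,
                      stringsAsFactors = FALSE)
  new_stand(trees, forest_type = forest_type, stage = stage, year = year)
}

#' Small deterministic example stand
#'
#' A fixed 12-tree mixed stand used in examples and smoke tests.
#'
#' @return A `stand` object.
#' @export
example_stand <- function() {
  trees <- data.frame(
    tree_id = 1:12,
    species_group = rep(c("beech", "spruce", "fir", "oak"), each = 3),
    dbh = c(18, 32, 55, 15, 28, 48, 22, 36, 61, 14, 41, 72),
    height = c(16, 24, 32, 14, 22, 30, 18, 25, 33, 12, 26, 34),
    status = "live",
    origin = "initial",
    stringsAsFactors = FALSE
  )
  new_stand(trees, forest_type = "beech_dominated", stage = "mature")
}
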