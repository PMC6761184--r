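# Clinical/molecular subgrouping: Group 1 hemispheric RTK, Group 2
# hemispheric RAS/MAPK, Group 3 midline RAS/MAPK.

#' Assign an infant-glioma subgroup from pathway class and tumor location
#'
#' \itemize{
#'   \item GROUP1: RTK-driven, hemispheric;
#'   \item GROUP2: RAS/MAPK-driven, hemispheric;
#'   \item GROUP3: RAS/MAPK-driven, midline;
#'   \item every other combination (midline RTK, OTHER/NONE pathway,
#'     location "other") is UNCLASSIFIED, with the rationale recorded.
#' }
#'
#' @param pathway one of "RTK", "RAS_MAPK", "OTHER", "NONE" (vectorised).
#' @param location one of "hemispheric", "midline", "other" (vectorised).
#' @return data frame with \code{group} and \code{rationale}.
#' @export
assign_subgroup <- function(pathway, location) {
  if (length(pathway) != length(location))
    stop("classification error: pathway and location lengths differ", call. = FALSE)
  if (any(is.na(location)) || !all(location %in% location_levels()))
    stop("classification error: missing or unknown tumor location", call. = FALSE)
  if (!all(pathway %in% c("RTK", "RAS_MAPK", "OTHER", "NONE")))
    stop("classification error: unknown pathway class", call. = FALSE)
  group <- rep("UNCLASSIFIED", length(pathway))
  group[pathway == "RTK" & location == "hemispheric"] <- "GROUP1"
  group[pathway == "RAS_MAPK" & location == "hemispheric"] <- "GROUP2"
  group[pathway == "RAS_MAPK" & location == "midline"] <- "GROUP3"
  data.frame(group = group,
             rationale = sprintf("%s/%s", pathway, location))
}

#' Summarise a classified cohort
#'
#' Counts and printed-style percentages (1 decimal, rounded half-up) for
#' driver frequencies, pathway by location, group sizes, histological grade
#' within group and extent of surgery within group. Percentages use the
#' denominators conventional for each table: the molecularly characterised
#' cohort for driver and pathway frequencies, the location stratum for
#' pathway-by-location, and the group size within groups.
#'
#' @param cohort data frame with columns \code{sample_id}, \code{driver},
#'   \code{pathway}, \code{location}, \code{group} and optionally
#'   \code{grade}, \code{histology}, \code{surgery}.
#' @param config pipeline configuration (reporting precision).
#' @return named list of summary data frames.
#' @export
cohort_summary <- function(cohort, config = default_config()) {
  dg <- config$rounding$digits
  if (nrow(cohort) == 0)
    return(list(drivers = data.frame(), pathway_by_location = data.frame(),
                groups = data.frame(), grade_by_group = data.frame(),
                surgery_by_group = data.frame()))
  n <- nrow(cohort)
  tab <- function(x, den) {
    t <- table(x)
    data.frame(level = names(t), n = as.integer(t),
               percent = pct(as.integer(t), den, dg), row.names = NULL)
  }
  drivers <- tab(factor(cohort$driver, levels = driver_levels()), n)
  drivers <- drivers[drivers$n > 0, , drop = FALSE]

  pbl <- do.call(rbind, lapply(intersect(location_levels(), cohort$location),
    function(loc) {
      sub <- cohort[cohort$location == loc, , drop = FALSE]
      t <- tab(factor(sub$pathway, c("RTK", "RAS_MAPK", "OTHER", "NONE")),
               nrow(sub))
      cbind(location = loc, t, n_location = nrow(sub))
    }))

  groups <- tab(factor(cohort$group,
                       c("GROUP1", "GROUP2", "GROUP3", "UNCLASSIFIED")), n)

  by_group <- function(col) {
    if (is.null(cohort[[col]])) return(data.frame())
    do.call(rbind, lapply(c("GROUP1", "GROUP2", "GROUP3"), function(g) {
      sub <- cohort[cohort$group == g, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      cbind(group = g, tab(sub[[col]], nrow(sub)), n_group = nrow(sub))
    }))
  }
  list(drivers = drivers,
       pathway_by_location = pbl,
       groups = groups,
       grade_by_group = by_group("grade"),
       histology_by_group = by_group("histology"),
       surgery_by_group = by_group("surgery"))
}

#' Headline cohort fractions
#'
#' The printed-style headline percentages for a classified cohort:
#' RAS/MAPK share of the cohort, KIAA1549-BRAF share, RTK share, fraction
#' of RTK tumors that are hemispheric, HGG (incl. mixed) within Group 1,
#' Group 2 share of hemispheric tumors, RAS/MAPK share of midline tumors,
#' BRAF-altered share of Group 3 and pilocytic share of Group 3.
#'
#' @param cohort classified cohort (needs \code{driver}, \code{pathway},
#'   \code{location}, \code{group}, \code{grade} and \code{histology}).
#' @param config pipeline configuration.
#' @return named numeric vector of percentages, with the underlying counts
#'   in \code{attr(,"counts")}.
#' @export
headline_fractions <- function(cohort, config = default_config()) {
  dg <- config$rounding$digits
  n <- nrow(cohort)
  rtk <- cohort$pathway == "RTK"
  g1 <- cohort$group == "GROUP1"
  g3 <- cohort$group == "GROUP3"
  hemi <- cohort$location == "hemispheric"
  mid <- cohort$location == "midline"
  braf <- cohort$driver %in% c("KIAA1549_BRAF", "BRAF_V600E")
  # mixed-grade tumors count as HGG for enrichment summaries
  hgg <- cohort$grade %in% c("HGG", "mixed")
  counts <- c(
    ras_mapk          = sum(cohort$pathway == "RAS_MAPK"),
    kiaa1549_braf     = sum(cohort$driver == "KIAA1549_BRAF"),
    rtk               = sum(rtk),
    rtk_hemispheric   = sum(rtk & hemi),
    group1_hgg        = sum(g1 & hgg),
    group2            = sum(cohort$group == "GROUP2"),
    midline_ras_mapk  = sum(mid & cohort$pathway == "RAS_MAPK"),
    group3_braf       = sum(g3 & braf),
    group3_pilocytic  = sum(g3 & grepl("pilocytic", cohort$histology,
                                       ignore.case = TRUE)))
  dens <- c(n, n, n, counts[["rtk"]], sum(g1), sum(hemi), sum(mid),
            sum(g3), sum(g3))
  out <- pct(counts, dens, dg)
  names(out) <- names(counts)
  attr(out, "counts") <- data.frame(name = names(counts),
                                    num = as.integer(counts),
                                    den = as.integer(dens))
  out
}
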