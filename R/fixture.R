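#' Deterministic 118-sample reference cohort
#'
#' A pure constructor (no randomness) for a cohort reproducing every
#' published marginal count of the molecularly characterised infant-glioma
#' cohort:
#' \itemize{
#'   \item 118 samples: 65 hemispheric + 53 midline;
#'   \item drivers: KIAA1549-BRAF 28, BRAF V600E 21, FGFR1-TACC1 3,
#'     FGFR1-TKD 2, PML-RAF1 1, MYBL1 gain 1 (RAS/MAPK total 56); ALK 12,
#'     ROS1 8, NTRK 7, MET 3 (RTK total 30, 29 hemispheric / 1 midline,
#'     25 HGG incl. mixed);
#'   \item subgroups 29 / 17 / 39; Group 1 histology 5 LGG + 21 HGG +
#'     3 mixed; Group 2 6/17 non-BRAF RAS/MAPK; Group 3 all LGG with 27
#'     pilocytic, 31 OPHG, 38/39 BRAF-altered;
#'   \item gross-total resections 12 / 9 / 3 per group.
#' }
#' Attributes the publication does not pin down jointly are filled
#' deterministically in sample-id order (see the methods vignette): Group
#' 2's drivers are 6 KIAA1549-BRAF, 5 V600E, 3 FGFR1-TACC1, 2 FGFR1-TKD,
#' 1 PML-RAF1; Group 3's single non-BRAF driver is the MYBL1 gain; the one
#' midline RTK tumor is a MET-fused HGG; the three mixed-grade Group 1
#' tumors are NTRK-fused; the 32 remaining unclassified samples alternate
#' OTHER/NONE. Ages are the group means and the \code{true_vaf} of V600E
#' samples is fixed at 0.30; both are synthetic fills, never acceptance
#' quantities.
#'
#' @return latent-truth data frame of 118 samples (same columns as
#'   \code{\link{generate_cohort}}).
#' @export
reference_cohort <- function() {
  row <- function(driver, location, grade, histology, opg = FALSE,
                  surgery = "partial", age = 5.0) {
    data.frame(true_driver = driver, location = location, grade = grade,
               histology = histology, opg_flag = opg, age_at_dx = age,
               surgery = surgery,
               true_vaf = if (driver == "BRAF_V600E") 0.30 else 0,
               partner_known = driver %in%
                 c("KIAA1549_BRAF", "FGFR1_TACC1", "PML_RAF1", "ALK_FUSION",
                   "ROS1_FUSION", "NTRK_FUSION"),
               stringsAsFactors = FALSE)
  }
  rep_rows <- function(k, ...) {
    r <- row(...)
    r[rep(1L, k), , drop = FALSE]
  }

  # --- Group 1: 29 hemispheric RTK (5 LGG ALK, 21 HGG, 3 mixed NTRK) ----
  g1 <- rbind(
    rep_rows(1, "ALK_FUSION", "hemispheric", "LGG", "ganglioglioma", age = 5.0),
    rep_rows(2, "ALK_FUSION", "hemispheric", "LGG", "diffuse astrocytoma", age = 5.0),
    rep_rows(2, "ALK_FUSION", "hemispheric", "LGG", "low-grade glioma, NOS", age = 5.0),
    rep_rows(7, "ALK_FUSION", "hemispheric", "HGG", "glioblastoma", age = 1.6),
    rep_rows(8, "ROS1_FUSION", "hemispheric", "HGG", "glioblastoma", age = 2.8),
    rep_rows(3, "NTRK_FUSION", "hemispheric", "mixed", "mixed glioma", age = 2.8),
    rep_rows(4, "NTRK_FUSION", "hemispheric", "HGG", "high-grade glioma, NOS", age = 2.8),
    rep_rows(2, "MET_FUSION", "hemispheric", "HGG", "glioblastoma", age = 2.8))
  g1$surgery <- rep(c("none", "none", "biopsy", "partial", "GTR"),
                    c(1, 1, 5, 10, 12))  # Table fill: 1 unknown recorded as none

  # --- Group 2: 17 hemispheric RAS/MAPK LGG (6 non-BRAF) ----------------
  g2 <- rbind(
    rep_rows(6, "KIAA1549_BRAF", "hemispheric", "LGG", "pilocytic astrocytoma", age = 9.0),
    rep_rows(5, "BRAF_V600E", "hemispheric", "LGG", "ganglioglioma", age = 9.0),
    rep_rows(3, "FGFR1_TACC1", "hemispheric", "LGG", "low-grade glioma, NOS", age = 9.0),
    rep_rows(2, "FGFR1_TKD", "hemispheric", "LGG", "diffuse astrocytoma", age = 9.0),
    rep_rows(1, "PML_RAF1", "hemispheric", "LGG", "other", age = 9.0))
  g2$histology[1:4] <- "pilocytic astrocytoma"   # Table: 4 pilocytic in Group 2
  g2$histology[5:6] <- "ganglioglioma"
  g2$surgery <- rep(c("none", "biopsy", "partial", "GTR"), c(1, 3, 4, 9))

  # --- Group 3: 39 midline RAS/MAPK LGG (38 BRAF + MYBL1 gain) ----------
  g3 <- rbind(
    rep_rows(22, "KIAA1549_BRAF", "midline", "LGG", "pilocytic astrocytoma", age = 7.5),
    rep_rows(16, "BRAF_V600E", "midline", "LGG", "low-grade glioma, NOS", age = 7.5),
    rep_rows(1, "MYBL1_GAIN", "midline", "LGG", "diffuse astrocytoma", age = 7.5))
  # histology fill to the printed Group 3 table: 27 pilocytic, 3 diffuse, 8 NOS, 1 other
  g3$histology <- rep(c("pilocytic astrocytoma", "diffuse astrocytoma",
                        "low-grade glioma, NOS", "other", "diffuse astrocytoma"),
                      c(27, 2, 8, 1, 1))
  g3$opg_flag <- rep(c(TRUE, FALSE), c(31, 8))   # 31/39 optic pathway/hypothalamic
  g3$surgery <- rep(c("none", "biopsy", "partial", "GTR", "none"),
                    c(1, 13, 21, 3, 1))

  # --- Unclassified: 1 midline MET HGG + 32 driver-OTHER/NONE -----------
  u_met <- row("MET_FUSION", "midline", "HGG", "glioblastoma", age = 2.8)
  rest_drivers <- rep(c("OTHER", "NONE"), 16)    # alternate in sample-id order
  rest_loc <- rep(c("hemispheric", "midline"), c(19, 13))
  u_rest <- do.call(rbind, lapply(seq_len(32), function(i)
    row(rest_drivers[i], rest_loc[i], "LGG", "other", age = 5.0)))

  cohort <- rbind(g1, g2, g3, u_met, u_rest)
  cohort <- cbind(sample_id = sprintf("IG%03d", seq_len(nrow(cohort))), cohort)
  rownames(cohort) <- NULL
  cohort
}
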