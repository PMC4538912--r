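#' Run the four dose engines on one phantom bundle
#'
#' Self-calibrates the simulated counts to the administered activity,
#' converts to total disintegrations, and runs LD, SK, SKD and RT. The
#' RT engine is evaluated on the union of the liver and lung masks (the
#' VOIs that are reported), everywhere else its map is zero.
#'
#' @param ph phantom bundle from [generate_phantom] (with a `counts`
#'   element, as produced by [generate_cohort]).
#' @param kernel voxel kernel from [build_voxel_kernel].
#' @return named list of dose map [voxel_grid]s: `LD`, `SK`, `SKD`, `RT`.
#' @export
phantom_doses <- function(ph, kernel) {
  act <- counts_to_activity(ph$counts, ph$spec$administered_Bq)
  n <- activity_to_disintegrations(act)
  rho <- ph$density
  targets <- ph$masks$liver$values > 0 | ph$masks$lung$values > 0
  list(
    LD = dose_ld(n, rho),
    SK = dose_sk(n, kernel),
    SKD = dose_skd(n, kernel, rho),
    RT = dose_rt(n, kernel, rho, targets = targets)
  )
}

#' Cohort VOI analysis: engine comparison and interface sensitivity
#'
#' For every phantom: computes all four engines' mean absorbed doses for
#' tumor, non-tumoral liver (NL) and lung (RL); builds remainder VOIs
#' excluding each margin around the liver--lung interface; and fits the
#' original-vs-remainder sensitivity regression across the cohort per
#' VOI and margin (on the reference RT doses).
#'
#' @param cohort result of [generate_cohort].
#' @param kernel voxel kernel from [build_voxel_kernel].
#' @param margins_mm exclusion margins (default 10, 20, 30 mm).
#' @return list with:
#'   \describe{
#'   \item{voi_means}{data.frame `phantom`, `engine`, `voi`
#'     (tumor/nl/lung), `mean_Gy`.}
#'   \item{engine_vs_rt}{data.frame of percent deviations of each
#'     engine's VOI mean dose from RT.}
#'   \item{remainder_means}{data.frame `phantom`, `engine`, `voi`,
#'     `margin_mm`, `mean_Gy` (margin 0 = original).}
#'   \item{fits}{data.frame `voi`, `margin_mm`, `slope`, `intercept`,
#'     `r_squared`, `mean_pct_change` from [sensitivity_fit] on RT.}
#'   }
#' @export
run_cohort_study <- function(cohort, kernel, margins_mm = c(10, 20, 30)) {
  engines <- c("LD", "SK", "SKD", "RT")
  voi_means <- NULL
  remainder_means <- NULL
  for (i in seq_along(cohort$phantoms)) {
    ph <- cohort$phantoms[[i]]
    d <- phantom_doses(ph, kernel)
    tum_all <- Reduce(`|`, lapply(ph$masks$tumors, function(m) m$values > 0),
                      array(FALSE, dim(ph$density$values)))
    vois <- list(tumor = tum_all, nl = ph$masks$nl, lung = ph$masks$lung)
    for (eng in engines) for (v in names(vois)) {
      if (v == "tumor" && !any(vois$tumor)) next
      voi_means <- rbind(voi_means, data.frame(
        phantom = i, engine = eng, voi = v,
        mean_Gy = mean_dose(d[[eng]], vois[[v]])))
    }
    for (mm in margins_mm) {
      rem <- interface_exclusion(ph$masks$liver, ph$masks$lung, mm)
      rem_nl <- with_values(rem$remainder_liver,
                            rem$remainder_liver$values *
                              (ph$masks$nl$values > 0))
      for (eng in engines) {
        remainder_means <- rbind(remainder_means, data.frame(
          phantom = i, engine = eng, voi = c("nl", "lung"),
          margin_mm = mm,
          mean_Gy = c(mean_dose(d[[eng]], rem_nl),
                      mean_dose(d[[eng]], rem$remainder_lung))))
      }
    }
  }
  # percent deviation of each engine from RT, per phantom and VOI
  rt <- voi_means[voi_means$engine == "RT", ]
  dev <- merge(voi_means[voi_means$engine != "RT", ], rt,
               by = c("phantom", "voi"), suffixes = c("", "_rt"))
  engine_vs_rt <- data.frame(
    phantom = dev$phantom, engine = dev$engine, voi = dev$voi,
    pct_dev = 100 * (dev$mean_Gy - dev$mean_Gy_rt) / dev$mean_Gy_rt)
  # sensitivity fits on the RT engine
  fits <- NULL
  for (v in c("nl", "lung")) for (mm in margins_mm) {
    orig <- voi_means[voi_means$engine == "RT" & voi_means$voi == v, ]
    rem <- remainder_means[remainder_means$engine == "RT" &
                             remainder_means$voi == v &
                             remainder_means$margin_mm == mm, ]
    m <- merge(orig, rem, by = "phantom", suffixes = c("_orig", "_rem"))
    f <- sensitivity_fit(m$mean_Gy_orig, m$mean_Gy_rem)
    fits <- rbind(fits, data.frame(
      voi = v, margin_mm = mm, slope = f$slope, intercept = f$intercept,
      r_squared = f$r_squared, mean_pct_change = f$mean_pct_change))
  }
  list(voi_means = voi_means, engine_vs_rt = engine_vs_rt,
       remainder_means = remainder_means, fits = fits)
}
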