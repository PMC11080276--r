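#' Group-level summary profile
#'
#' A `group_profile` carries everything needed to simulate one study group:
#' its size, the marginal distribution of every categorical variable (keyed
#' by state code), and per continuous variable either a mean/SD pair
#' (sampled as a normal truncated at 0) or a median/quartile triple (sampled
#' log-normally with parameters matched to the median and the quartile
#' ratio).
#'
#' @param group group label.
#' @param n positive integer group size.
#' @param categorical named list; per variable a probability vector named by
#'   state code, each summing to 1 (within 1e-9 after normalization).
#' @param continuous named list; per variable either
#'   `list(mean =, sd =)` or `list(median =, p25 =, p75 =)`.
#' @return An object of class `"group_profile"`.
#' @export
group_profile <- function(group, n, categorical, continuous) {
  stopifnot(length(group) == 1L, n > 0)
  for (nm in names(categorical)) {
    p <- categorical[[nm]]
    if (any(p < 0)) stop("negative marginal in '", nm, "'")
    s <- sum(p)
    if (s <= 0) stop("empty marginal for '", nm, "'")
    categorical[[nm]] <- p / s
  }
  for (nm in names(continuous)) {
    cs <- continuous[[nm]]
    if (!is.null(cs$sd) && cs$sd < 0) stop("negative sd for '", nm, "'")
    if (!is.null(cs$p25) && !(cs$p25 <= cs$median && cs$median <= cs$p75))
      stop("quartiles of '", nm, "' must bracket the median")
  }
  structure(list(group = group, n = as.integer(n),
                 categorical = categorical, continuous = continuous),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat(sprintf("<group_profile> %s: n = %d, %d categorical, %d continuous\n",
              x$group, x$n, length(x$categorical), length(x$continuous)))
  invisible(x)
}

cat_counts <- function(codes, counts) {
  stats::setNames(counts / sum(counts), as.character(codes))
}

#' Built-in study group profiles
#'
#' The four group profiles of the source study: 1175 controls, 1163 type 2
#' diabetes (T2DM) cases, 982 coronary heart disease (CAD) cases and 504
#' comorbidity cases, carrying every published categorical count and
#' continuous summary. Categorical marginals are normalized counts; group
#' sizes are exact.
#'
#' Three published entries are physiologically impossible as printed and are
#' presumed transcription artifacts: the comorbidity heart-rate mean (6.55,
#' restored to 76.55), the T2DM fasting-glucose upper quartile (1.40,
#' restored to 11.40), and truncated leading digits on the upper quartiles
#' of triglycerides in all groups and of comorbidity fasting glucose
#' (restored to the smallest digit making the quartile exceed the median).
#' Set `correct_typos = FALSE` to keep the verbatim values.
#'
#' @param correct_typos apply the corrections described above (default
#'   `TRUE`).
#' @return Named list of four [group_profile()] objects
#'   (`control`, `T2DM`, `CAD`, `comorbidity`).
#' @export
reference_profiles <- function(correct_typos = TRUE) {
  # per variable: state codes, then per-group counts (control/T2DM/CAD/comorbidity)
  cat_tab <- list(
    sex = list(codes = 1:2,
               control = c(726, 449), T2DM = c(635, 528),
               CAD = c(641, 341), comorbidity = c(312, 192)),
    area = list(codes = 1:3,
                control = c(29, 48, 1098), T2DM = c(447, 187, 529),
                CAD = c(378, 114, 490), comorbidity = c(142, 90, 272)),
    education = list(codes = 1:3,
                     control = c(8, 259, 908), T2DM = c(92, 936, 135),
                     CAD = c(95, 812, 75), comorbidity = c(44, 418, 42)),
    marriage = list(codes = 1:2,
                    control = c(853, 322), T2DM = c(1099, 64),
                    CAD = c(949, 33), comorbidity = c(482, 22)),
    occupation = list(codes = 1:5,
                      control = c(62, 56, 785, 68, 204),
                      T2DM = c(368, 166, 137, 4, 488),
                      CAD = c(270, 62, 123, 1, 526),
                      comorbidity = c(120, 30, 61, 1, 292)),
    fhx_dm = list(codes = 0:1,
                  control = c(1022, 153), T2DM = c(938, 225),
                  CAD = c(943, 39), comorbidity = c(440, 64)),
    fhx_cad = list(codes = 0:1,
                   control = c(1090, 85), T2DM = c(1122, 41),
                   CAD = c(921, 61), comorbidity = c(466, 38)),
    smoke = list(codes = 1:4,
                 control = c(933, 99, 114, 29), T2DM = c(866, 63, 196, 38),
                 CAD = c(654, 71, 183, 74), comorbidity = c(357, 37, 78, 32)),
    drink = list(codes = 1:4,
                 control = c(771, 354, 36, 14), T2DM = c(944, 133, 52, 34),
                 CAD = c(781, 108, 63, 30), comorbidity = c(412, 50, 22, 20)),
    staple = list(codes = 1:3,
                  control = c(626, 489, 64), T2DM = c(708, 379, 76),
                  CAD = c(291, 567, 124), comorbidity = c(193, 279, 32)),
    meat = list(codes = 1:3,
                control = c(29, 483, 663), T2DM = c(152, 486, 525),
                CAD = c(134, 497, 351), comorbidity = c(71, 255, 178)),
    vegetable = list(codes = 1:3,
                     control = c(24, 434, 717), T2DM = c(35, 521, 607),
                     CAD = c(88, 499, 395), comorbidity = c(29, 252, 223)),
    fruit = list(codes = 1:4,
                 control = c(15, 572, 556, 32), T2DM = c(221, 724, 203, 15),
                 CAD = c(93, 754, 123, 12), comorbidity = c(64, 367, 64, 9)),
    sweet = list(codes = 1:4,
                 control = c(278, 715, 162, 20), T2DM = c(760, 274, 87, 42),
                 CAD = c(364, 522, 78, 18), comorbidity = c(300, 173, 23, 8)),
    exercise = list(codes = 0:1,
                    control = c(330, 845), T2DM = c(614, 549),
                    CAD = c(524, 458), comorbidity = c(280, 224)),
    sleep = list(codes = 1:4,
                 control = c(40, 594, 523, 18), T2DM = c(130, 614, 402, 17),
                 CAD = c(199, 435, 270, 78), comorbidity = c(106, 217, 152, 29)),
    central_obesity = list(codes = 0:1,
                           control = c(897, 281), T2DM = c(719, 444),
                           CAD = c(646, 336), comorbidity = c(287, 217))
  )
  ms <- function(mean, sd) list(mean = mean, sd = sd)
  mq <- function(median, p25, p75) list(median = median, p25 = p25, p75 = p75)
  cont_tab <- list(
    age = list(control = ms(40.79, 14.02), T2DM = ms(59.98, 12.06),
               CAD = ms(67.16, 11.75), comorbidity = ms(67.65, 10.38)),
    bmi = list(control = ms(23.43, 3.40), T2DM = ms(23.66, 3.98),
               CAD = ms(22.99, 3.21), comorbidity = ms(23.60, 3.28)),
    sbp = list(control = ms(122.70, 16.11), T2DM = ms(135.79, 21.85),
               CAD = ms(139.34, 21.21), comorbidity = ms(142.15, 22.04)),
    dbp = list(control = ms(74.05, 11.05), T2DM = ms(77.52, 12.06),
               CAD = ms(77.99, 12.10), comorbidity = ms(77.17, 12.06)),
    heart_rate = list(control = ms(79.49, 12.15), T2DM = ms(81.44, 12.18),
                      CAD = ms(74.12, 12.44),
                      comorbidity = if (correct_typos) ms(76.55, 11.64)
                                    else ms(6.55, 11.64)),
    fbg = list(control = mq(4.87, 4.56, 5.22),
               T2DM = if (correct_typos) mq(7.80, 5.64, 11.40)
                      else mq(7.80, 5.64, 1.40),
               CAD = mq(5.03, 4.57, 5.70),
               comorbidity = if (correct_typos) mq(7.61, 5.47, 9.73)
                             else mq(7.61, 5.47, 0.73)),
    tg = list(control = if (correct_typos) mq(1.13, 0.81, 1.72)
                        else mq(1.13, 0.81, 0.72),
              T2DM = if (correct_typos) mq(1.47, 1.00, 2.21)
                     else mq(1.47, 1.00, 0.21),
              CAD = if (correct_typos) mq(1.29, 0.94, 1.81)
                    else mq(1.29, 0.94, 0.81),
              comorbidity = if (correct_typos) mq(1.48, 1.04, 2.02)
                            else mq(1.48, 1.04, 0.02)),
    tc = list(control = ms(5.20, 1.10), T2DM = ms(5.16, 1.47),
              CAD = ms(4.81, 1.31), comorbidity = ms(4.63, 1.35)),
    hdl = list(control = ms(1.37, 0.36), T2DM = ms(1.21, 0.47),
               CAD = ms(1.21, 0.33), comorbidity = ms(1.14, 0.31)),
    ldl = list(control = ms(2.67, 1.36), T2DM = ms(3.14, 1.28),
               CAD = ms(2.89, 1.12), comorbidity = ms(2.68, 1.08))
  )
  sizes <- c(control = 1175L, T2DM = 1163L, CAD = 982L, comorbidity = 504L)
  out <- lapply(names(sizes), function(g) {
    group_profile(
      group = g, n = sizes[[g]],
      categorical = lapply(cat_tab, function(v) cat_counts(v$codes, v[[g]])),
      continuous = lapply(cont_tab, function(v) {
        cs <- v[[g]]
        if (!correct_typos && !is.null(cs$p25) && cs$p75 < cs$median)
          cs$p75 <- cs$median  # keep verbatim-mode profiles constructible
        cs
      })
    )
  })
  stats::setNames(out, names(sizes))
}
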