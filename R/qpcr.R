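#' Validate the U6 reference gene across stages
#'
#' The reference is accepted when the largest absolute difference between
#' stage means of its Cq is strictly below `max_diff` cycles.
#'
#' @param cq A Cq table: tibble `mirna`, `stage_week`, `replicate`, `cq`.
#' @param reference Reference id (default `"U6"`).
#' @param max_diff Acceptance bound in cycles (default 0.6, exclusive).
#' @return One-row tibble `valid`, `max_abs_diff`, `n_stages`, with the
#'   per-stage means as attribute `stage_means`.
#' @export
validate_reference <- function(cq, reference = "U6", max_diff = 0.6) {
  ref <- dplyr::filter(cq, .data$mirna == reference)
  stages <- sort(unique(cq$stage_week))
  missing <- setdiff(stages, unique(ref$stage_week))
  if (length(missing) || !nrow(ref)) {
    stop("reference '", reference, "' missing at stage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  means <- ref |>
    dplyr::group_by(.data$stage_week) |>
    dplyr::summarise(mean_cq = mean(.data$cq), .groups = "drop")
  d <- max(abs(outer(means$mean_cq, means$mean_cq, "-")))
  out <- tibble::tibble(valid = d < max_diff, max_abs_diff = d,
                        n_stages = nrow(means))
  attr(out, "stage_means") <- means
  out
}

#' Per-replicate delta-Cq normalisation to the reference gene
#'
#' `dCq = Cq_miRNA - Cq_reference`. By default the reference Cq is taken
#' replicate-matched (`pairing = "replicate"`), so the reference's
#' measurement noise enters the replicate-to-replicate variance and the
#' downstream stage-wise tests are correctly calibrated. With
#' `pairing = "stage_mean"` the stage-mean reference is subtracted instead;
#' stage means (and hence all 2^-ddCq levels) are identical under both
#' pairings, but the stage-mean variant hides the shared reference error
#' from the within-stage variance, which makes stage comparisons
#' anticonservative — use it only when replicate correspondence across
#' plates is meaningless.
#'
#' @inheritParams validate_reference
#' @param pairing `"replicate"` (default) or `"stage_mean"`.
#' @return The non-reference rows of `cq` with an added `dcq` column.
#' @export
delta_cq <- function(cq, reference = "U6", pairing = c("replicate", "stage_mean")) {
  pairing <- match.arg(pairing)
  ref <- dplyr::filter(cq, .data$mirna == reference)
  if (!nrow(ref)) stop("reference '", reference, "' not present", call. = FALSE)
  x <- dplyr::filter(cq, .data$mirna != reference)
  if (pairing == "stage_mean") {
    ref_means <- ref |>
      dplyr::group_by(.data$stage_week) |>
      dplyr::summarise(ref_cq = mean(.data$cq), .groups = "drop")
    x <- dplyr::left_join(x, ref_means, by = "stage_week")
  } else {
    x <- dplyr::left_join(
      x, dplyr::select(ref, "stage_week", "replicate", ref_cq = "cq"),
      by = c("stage_week", "replicate")
    )
  }
  if (anyNA(x$ref_cq)) {
    stop("reference missing for some stage", if (pairing == "replicate")
      "/replicate combination (consider pairing = \"stage_mean\")", call. = FALSE)
  }
  dplyr::mutate(x, dcq = .data$cq - .data$ref_cq, ref_cq = NULL)
}

#' Relative expression profiles by the 2^-ddCq method
#'
#' For each miRNA and stage: `ddCq(s) = mean dCq(s) - mean dCq(baseline)` and
#' the relative level is `2^-ddCq`, so the baseline stage is exactly 1.
#' Per-replicate relative levels give the dispersion estimate.
#'
#' @param dcq A [delta_cq()] result.
#' @param baseline_stage Baseline week (default 10, the earliest sampled).
#' @return A tibble of class `mir_profiles`: `mirna`, `stage_week`, `n`,
#'   `mean_dcq`, `ddcq`, `level`, `level_sd`.
#' @export
rel_expression <- function(dcq, baseline_stage = 10) {
  if (!baseline_stage %in% dcq$stage_week) {
    stop("baseline stage ", baseline_stage, " not present", call. = FALSE)
  }
  prof <- dcq |>
    dplyr::group_by(.data$mirna, .data$stage_week) |>
    dplyr::summarise(n = dplyr::n(), mean_dcq = mean(.data$dcq),
                     sd_lin = sd(2^-.data$dcq), .groups = "drop_last") |>
    dplyr::mutate(
      ddcq = .data$mean_dcq - .data$mean_dcq[.data$stage_week == baseline_stage],
      level = 2^-.data$ddcq,
      # sd of the per-replicate 2^-ddCq values (replicate levels relative to
      # the baseline-stage mean dCq)
      level_sd = .data$sd_lin * 2^.data$mean_dcq[.data$stage_week == baseline_stage]
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"sd_lin")
  new_mir_tbl(prof, "mir_profiles", baseline_stage = baseline_stage)
}

#' One-way fixed-effects ANOVA of delta-Cq values across stages
#'
#' Classic one-way ANOVA on the replicate dCq values of the given stages; for
#' two stages this is equivalent to the two-sample t-test (F = t^2). When
#' both the between- and within-stage variances are zero the p-value is 1 by
#' convention; with zero within-stage variance but distinct means it is 0.
#'
#' @param dcq A [delta_cq()] result (or any tibble with `mirna`,
#'   `stage_week`, `dcq`).
#' @param mirna miRNA id to test.
#' @param stages Stages to include (>= 2, each with >= 2 replicates).
#' @return The p-value.
#' @export
stage_anova <- function(dcq, mirna, stages) {
  x <- dcq[dcq$mirna == mirna & dcq$stage_week %in% stages, ]
  if (length(unique(x$stage_week)) < 2L) {
    stop("ANOVA needs at least two stages", call. = FALSE)
  }
  if (min(table(x$stage_week)) < 2L) {
    stop("ANOVA needs at least two replicates per stage", call. = FALSE)
  }
  mu <- tapply(x$dcq, x$stage_week, mean)
  ss_between <- sum(tapply(x$dcq, x$stage_week, length) * (mu - mean(x$dcq))^2)
  ss_within <- sum((x$dcq - mu[as.character(x$stage_week)])^2)
  if (ss_within < 1e-12) {
    return(if (ss_between < 1e-12) 1 else 0)
  }
  fit <- anova(lm(dcq ~ factor(stage_week), data = x))
  fit$`Pr(>F)`[1]
}

#' Classify miRNAs with the temporal puberty-onset panel rule
#'
#' A miRNA is a panel biomarker iff all three hold:
#' * `early_ok` — its expression is low and stable before onset. With the
#'   default `early_rule = "low_level"` the pooled pre-onset dCq must be
#'   significantly higher (lower expression) than at the onset week
#'   (p < `alpha_stable`); with `early_rule = "stability"` the pre-onset
#'   stages must show no significant change (ANOVA p >= `alpha_stable`).
#' * `onset_jump` — expression rises significantly from the week before
#'   onset to the onset week (pairwise test p < `alpha_jump` and the level
#'   increases).
#' * `sustained` — for every later week the level either stays at or above
#'   the onset-week level, or any decrease is not significant at
#'   `alpha_drop`. Transient responders (rise then significant fall back)
#'   fail here.
#'
#' @param dcq A [delta_cq()] result covering all stages.
#' @param baseline_stage Baseline week for relative levels.
#' @param onset_pair Integer pair `(week before onset, onset week)`,
#'   default `c(12, 13)`.
#' @param alpha_stable,alpha_jump,alpha_drop Significance levels of the three
#'   flags (defaults 0.05, 0.01, 0.05).
#' @param early_rule `"low_level"` (default) or `"stability"`; see above.
#' @return A tibble of class `mir_panel`: `mirna`, the three flags, their
#'   p-values, and `verdict` (`TRUE` = panel biomarker).
#' @export
panel_classify <- function(dcq, baseline_stage = 10, onset_pair = c(12L, 13L),
                           alpha_stable = 0.05, alpha_jump = 0.01,
                           alpha_drop = 0.05,
                           early_rule = c("low_level", "stability")) {
  early_rule <- match.arg(early_rule)
  stages <- sort(unique(dcq$stage_week))
  if (!all(onset_pair %in% stages)) {
    stop("onset stages ", paste(onset_pair, collapse = ","),
         " not present in the Cq table", call. = FALSE)
  }
  onset <- onset_pair[2]
  early_stages <- stages[stages < onset]
  late_stages <- stages[stages > onset]
  prof <- rel_expression(dcq, baseline_stage)

  per_mirna <- function(m) {
    pm <- prof[prof$mirna == m, ]
    lev <- setNames(pm$level, pm$stage_week)

    if (early_rule == "low_level") {
      pooled <- dplyr::mutate(
        dcq[dcq$mirna == m & dcq$stage_week %in% c(early_stages, onset), ],
        stage_week = ifelse(.data$stage_week < onset, -1L, .data$stage_week)
      )
      p_early <- stage_anova(pooled, m, c(-1L, onset))
      early_mean <- mean(dcq$dcq[dcq$mirna == m & dcq$stage_week < onset])
      onset_mean <- mean(dcq$dcq[dcq$mirna == m & dcq$stage_week == onset])
      early_ok <- p_early < alpha_stable && early_mean > onset_mean
    } else {
      p_early <- stage_anova(dcq, m, early_stages)
      early_ok <- p_early >= alpha_stable
    }

    p_jump <- stage_anova(dcq, m, onset_pair)
    onset_jump <- p_jump < alpha_jump &&
      lev[as.character(onset)] > lev[as.character(onset_pair[1])]

    sustained <- TRUE
    for (w in late_stages) {
      if (lev[as.character(w)] >= lev[as.character(onset)]) next
      p_w <- stage_anova(dcq, m, c(onset, w))
      if (p_w < alpha_drop) { sustained <- FALSE; break }
    }

    tibble::tibble(
      mirna = m, early_ok = early_ok, onset_jump = onset_jump,
      sustained = sustained, p_early = p_early, p_jump = p_jump,
      verdict = early_ok && onset_jump && sustained
    )
  }

  out <- purrr::map_dfr(unique(dcq$mirna), per_mirna)
  new_mir_tbl(out, "mir_panel", early_rule = early_rule,
              onset_pair = onset_pair)
}

#' @describeIn panel_classify One-row summary: miRNAs tested, panel size and
#'   panel members.
#' @param x A `mir_panel` object.
#' @param ... Unused.
#' @method glance mir_panel
#' @export
glance.mir_panel <- function(x, ...) {
  tibble::tibble(
    n_mirna = nrow(x),
    n_panel = sum(x$verdict),
    panel = paste(x$mirna[x$verdict], collapse = ",")
  )
}

#' @describeIn rel_expression Fig-3-style plot of relative levels by stage
#'   with replicate-sd error bars.
#' @param object A `mir_profiles` object.
#' @param ... Unused.
#' @method autoplot mir_profiles
#' @export
autoplot.mir_profiles <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$stage_week, .data$level)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$level - .data$level_sd, 0),
                                        ymax = .data$level + .data$level_sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~mirna, scales = "free_y") +
    ggplot2::labs(x = "age (weeks)", y = "relative expression (2^-ddCq)") +
    ggplot2::theme_minimal()
}
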