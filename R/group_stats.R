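#' One-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Small tie-free samples
#' (both arms <= 8) are evaluated by exact enumeration; larger or tied
#' samples use the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param tail `"right"` tests the alternative that `x` is stochastically
#'   greater than `y`; `"left"` the reverse.
#' @return List with `statistic` (U, the number of (x, y) pairs with
#'   `x > y`, ties counted 1/2), `p` and `tail`.
#' @export
#' @examples
#' mann_whitney_u(c(4, 5, 6), c(1, 2, 3), tail = "right")$p  # 0.05
mann_whitney_u <- function(x, y, tail = c("right", "left")) {
  tail <- match.arg(tail)
  if (!length(x) || !length(y)) stop("both arms must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && length(x) <= 8 && length(y) <= 8
  alt <- if (tail == "right") "greater" else "less"
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = use_exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, tail = tail)
}

#' One-tailed Wilcoxon signed-rank test for paired samples
#'
#' Paired comparison after discarding zero differences; exact for n <= 20
#' without ties, otherwise the normal approximation with tie/zero handling
#' and continuity correction.
#'
#' @param pre,post Paired numeric vectors of equal length.
#' @param tail `"right"` tests pre > post; `"left"` tests pre < post.
#' @return List with `statistic` (W, sum of positive-difference ranks),
#'   `p`, `tail` and `n_eff` (pairs remaining after zero removal).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(5, 7, 9, 12, 20), 1:5, tail = "right")$p  # 1/32
wilcoxon_signed_rank <- function(pre, post, tail = c("right", "left")) {
  tail <- match.arg(tail)
  if (length(pre) != length(post)) stop("`pre` and `post` must be paired")
  d <- pre - post
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero: no information")
  if (length(d) < 5) {
    warning("fewer than 5 non-zero paired differences; the test has ",
            "little resolution")
  }
  has_ties <- anyDuplicated(abs(d)) > 0
  use_exact <- !has_ties && length(d) <= 20
  alt <- if (tail == "right") "greater" else "less"
  ht <- suppressWarnings(
    stats::wilcox.test(pre, post, paired = TRUE, alternative = alt,
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, tail = tail,
       n_eff = length(d))
}

#' Bonferroni correction
#'
#' @param p_raw Vector of raw p-values forming one family.
#' @param m_corr Family size (defaults to `length(p_raw)`).
#' @return Adjusted p-values, `min(1, m_corr * p_raw)`.
#' @export
bonferroni <- function(p_raw, m_corr = length(p_raw)) {
  if (m_corr < 1) stop("m_corr must be >= 1")
  pmin(1, m_corr * p_raw)
}

#' Directional group comparisons of contact-mean biomarkers
#'
#' Runs the two comparison designs separately for responders and
#' non-responders, per band and feature:
#'
#' * `tc_vs_ntc_pre`: pre-operative contact means of TC contacts vs non-TC
#'   contacts (unpaired, one-tailed: TC greater).
#' * `pre_vs_post_ntc`: paired pre vs post contact means of non-TC
#'   contacts; both tails are evaluated and the smaller one-tailed p is
#'   reported with its direction.
#'
#' Bonferroni correction is applied within each group-by-design family
#' (2 features x 4 bands = 8 tests at the canonical bands). Significance is
#' declared at adjusted p < `alpha`.
#'
#' @param contact_means Normalized contact means from [contact_average()].
#' @param contacts Contact metadata (`patient_id`, `channel_name`,
#'   `is_tc`).
#' @param outcomes Per-patient outcome tibble (`patient_id`, `outcome` in
#'   `"responder"` / `"non_responder"`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble with one row per group x design x band x feature:
#'   `statistic`, `p_raw`, `p_adjusted`, `tail`, `significant`, `n_x`,
#'   `n_y` (arm sizes; for paired design both equal the pair count).
#' @export
run_comparisons <- function(contact_means, contacts, outcomes,
                            alpha = 0.05) {
  if (!isTRUE(attr(contact_means, "normalized"))) {
    warning("contact means do not appear to be within-subject normalized")
  }
  fcols <- feature_cols(contact_means)
  cm <- dplyr::left_join(contact_means,
                         contacts[, c("patient_id", "channel_name", "is_tc")],
                         by = c("patient_id", "channel_name"))
  cm <- dplyr::left_join(cm, outcomes, by = "patient_id")
  if (anyNA(cm$is_tc) || anyNA(cm$outcome)) {
    stop("contact metadata or outcomes missing for some contacts")
  }
  bands <- intersect(band_names(), unique(cm$band))
  out <- list()
  for (grp in c("responders", "non_responders")) {
    lab <- if (grp == "responders") "responder" else "non_responder"
    gcm <- cm[cm$outcome == lab, , drop = FALSE]
    if (!nrow(gcm)) {
      warning("no contacts in group ", grp, "; group skipped")
      next
    }
    m_corr <- length(bands) * length(fcols)

    # design 1: TC vs non-TC, pre-operative, tail TC > non-TC
    rows1 <- list()
    for (b in bands) for (fc in fcols) {
      pre <- gcm[gcm$period == "pre" & gcm$band == b, , drop = FALSE]
      xv <- pre[[fc]][pre$is_tc]
      yv <- pre[[fc]][!pre$is_tc]
      if (!length(xv) || !length(yv)) next
      ht <- mann_whitney_u(xv, yv, tail = "right")
      rows1[[length(rows1) + 1L]] <- tibble::tibble(
        group = grp, design = "tc_vs_ntc_pre", band = b, feature = fc,
        statistic = ht$statistic, p_raw = ht$p, tail = ht$tail,
        n_x = length(xv), n_y = length(yv))
    }

    # design 2: paired pre vs post on non-TC contacts, better tail reported
    rows2 <- list()
    ntc <- gcm[!gcm$is_tc, , drop = FALSE]
    for (b in bands) for (fc in fcols) {
      sub <- ntc[ntc$band == b, c("patient_id", "channel_name", "period", fc)]
      wide <- tidyr::pivot_wider(sub, names_from = "period",
                                 values_from = dplyr::all_of(fc))
      wide <- wide[!is.na(wide$pre) & !is.na(wide$post), , drop = FALSE]
      if (nrow(wide) < 5) next
      hr <- wilcoxon_signed_rank(wide$pre, wide$post, tail = "right")
      hl <- wilcoxon_signed_rank(wide$pre, wide$post, tail = "left")
      ht <- if (hr$p <= hl$p) hr else hl
      rows2[[length(rows2) + 1L]] <- tibble::tibble(
        group = grp, design = "pre_vs_post_ntc", band = b, feature = fc,
        statistic = ht$statistic, p_raw = ht$p, tail = ht$tail,
        n_x = nrow(wide), n_y = nrow(wide))
    }

    for (rows in list(rows1, rows2)) {
      if (!length(rows)) next
      fam <- dplyr::bind_rows(rows)
      fam$p_adjusted <- bonferroni(fam$p_raw, m_corr = m_corr)
      fam$significant <- fam$p_adjusted < alpha
      out[[length(out) + 1L]] <- fam
    }
  }
  res <- dplyr::bind_rows(out)
  res[, c("group", "design", "band", "feature", "statistic", "p_raw",
          "p_adjusted", "tail", "significant", "n_x", "n_y")]
}

#' Notched box plots of contact-mean biomarkers
#'
#' Draws, per band and feature, notched box plots of TC, non-TC
#' pre-operative and non-TC post-operative contact means for one outcome
#' group -- the visual companion of [run_comparisons()]. Requires ggplot2.
#'
#' @param contact_means Normalized contact means.
#' @param contacts,outcomes Metadata as in [run_comparisons()].
#' @param group `"responders"` or `"non_responders"`.
#' @return A ggplot object.
#' @export
plot_comparisons <- function(contact_means, contacts, outcomes,
                             group = "responders") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_comparisons requires the ggplot2 package")
  }
  lab <- if (group == "responders") "responder" else "non_responder"
  cm <- dplyr::left_join(contact_means,
                         contacts[, c("patient_id", "channel_name", "is_tc")],
                         by = c("patient_id", "channel_name"))
  cm <- dplyr::left_join(cm, outcomes, by = "patient_id")
  cm <- cm[cm$outcome == lab, , drop = FALSE]
  cm$arm <- ifelse(cm$is_tc, "TC",
                   ifelse(cm$period == "pre", "nTC-pre", "nTC-post"))
  cm <- cm[!(cm$is_tc & cm$period == "post"), , drop = FALSE]
  long <- tidyr::pivot_longer(cm, dplyr::all_of(feature_cols(cm)),
                              names_to = "feature", values_to = "value")
  long$arm <- factor(long$arm, levels = c("TC", "nTC-pre", "nTC-post"))
  long$band <- factor(long$band, levels = band_names())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value)) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.size = 0.5) +
    ggplot2::facet_grid(feature ~ band, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized contact mean",
                  title = paste("Contact-mean biomarkers:", group))
}
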