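#' Exact Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences. Zero
#' differences are dropped; ties among the absolute differences receive
#' mid-ranks. For n <= `exact_max` the p-value is exact, computed from the
#' full sign-flip distribution of the rank sum (every one of the 2^n sign
#' assignments, accumulated by convolution over the doubled ranks so
#' mid-ranks stay on an integer grid); beyond that a normal approximation
#' with continuity correction and tie-corrected variance is used.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_max largest n for which the exact distribution is
#'   enumerated (default 25).
#' @return A list with `statistic` (sum of negative ranks), `p_value`
#'   (two-sided), `n` (non-zero differences used), `method`, and
#'   `degenerate` (TRUE when all differences are zero; then p = 1).
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25L) {
  d <- differences[is.finite(differences)]
  nz <- d[d != 0]
  if (!length(nz)) {
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate",
                degenerate = TRUE))
  }
  if (length(nz) < 3L) {
    stop_irritmap("At least 3 non-zero differences are required.",
                  "irritmap_stats_error")
  }
  r <- rank(abs(nz))  # mid-ranks for ties
  w_neg <- sum(r[nz < 0])
  mu <- sum(r) / 2
  n <- length(nz)
  if (n <= exact_max) {
    # distribution of the doubled rank sum under random sign flips
    r2 <- round(2 * r)
    probs <- 1
    for (ri in r2) {
      ext <- c(probs, numeric(ri)) + c(numeric(ri), probs)
      probs <- ext / 2
    }
    support <- seq_along(probs) - 1L  # doubled-rank sums
    dev <- abs(support - 2 * mu)
    p <- sum(probs[dev >= round(2 * abs(w_neg - mu)) - 1e-9])
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(w_neg - mu) - 0.5) / sigma
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal"
  }
  list(statistic = w_neg, p_value = min(p, 1), n = n, method = method,
       degenerate = FALSE)
}

#' Normality-gated paired comparison
#'
#' The target-versus-control scheme: a Shapiro-Wilk test on the paired
#' differences decides between the paired t-test (normal) and the Wilcoxon
#' signed-rank test (non-normal). Significance stars follow the usual
#' convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param target,control paired measurement vectors (same length >= 3, one
#'   value per zone).
#' @param alpha_normality Shapiro-Wilk level for the normality gate.
#' @param marker optional marker name carried into the result.
#' @return A one-row tibble: `marker`, `test` (`"paired_t"`, `"wilcoxon"`,
#'   or `"degenerate"`), `statistic`, `p_value`, `direction`, `n_pairs`,
#'   `normality_p`, `stars`.
#' @export
paired_compare <- function(target, control, alpha_normality = 0.05,
                           marker = NA_character_) {
  if (length(target) != length(control) || length(target) < 3L) {
    stop_irritmap("`target` and `control` must be paired with length >= 3.",
                  "irritmap_stats_error")
  }
  d <- target - control
  n <- length(d)
  if (all(d == 0)) {
    return(tibble::tibble(marker = marker, test = "degenerate",
                          statistic = 0, p_value = 1, direction = "none",
                          n_pairs = n, normality_p = NA_real_, stars = ""))
  }
  if (sd(d) == 0) {
    # identical non-zero differences: normality is unassessable and the t
    # statistic diverges; fall back to the distribution-free test
    wt <- wilcoxon_signed_rank(d)
    return(finish_test(marker, "wilcoxon", wt$statistic, wt$p_value, d, n,
                       NA_real_))
  }
  np <- shapiro.test(d)$p.value
  if (np >= alpha_normality) {
    tt <- t.test(d)
    finish_test(marker, "paired_t", unname(tt$statistic), tt$p.value, d, n,
                np)
  } else {
    wt <- wilcoxon_signed_rank(d)
    finish_test(marker, "wilcoxon", wt$statistic, wt$p_value, d, n, np)
  }
}

finish_test <- function(marker, test, statistic, p, d, n, normality_p) {
  tibble::tibble(
    marker = marker, test = test, statistic = statistic, p_value = p,
    direction = if (mean(d) > 0) "increase" else if (mean(d) < 0)
      "decrease" else "none",
    n_pairs = n, normality_p = normality_p, stars = p_stars(p))
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   otherwise `""`.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Per-marker summary of a paired histology table
#'
#' Averages the replicate measurements to one value per zone and region,
#' then runs the normality-gated paired comparison per marker. Means and
#' SDs are reported per region together with the test outcome; no
#' multiple-testing correction is applied by default (each marker is
#' reported at its nominal level), but Holm correction can be requested.
#'
#' @param table long measurement tibble (columns `zone`, `marker`,
#'   `region` in `"target"`/`"control"`, `value`; replicate rows allowed).
#' @param alpha_normality Shapiro-Wilk level for the gate.
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return A tibble with one row per marker: region means/SDs, `n_pairs`,
#'   test, statistic, p-value, direction and stars.
#' @export
summarize_markers <- function(table, alpha_normality = 0.05,
                              p_adjust = "none") {
  need <- c("zone", "marker", "region", "value")
  if (!all(need %in% names(table))) {
    stop_irritmap("`table` needs columns zone, marker, region, value.",
                  "irritmap_config_error")
  }
  zm <- histology_zone_means(table)
  out <- zm |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(function(g, key) {
      res <- paired_compare(g$target, g$control,
                            alpha_normality = alpha_normality)
      tibble::tibble(
        n_pairs = nrow(g),
        target_mean = mean(g$target), target_sd = sd(g$target),
        control_mean = mean(g$control), control_sd = sd(g$control),
        test = res$test, statistic = res$statistic,
        p_value = res$p_value, direction = res$direction,
        normality_p = res$normality_p)
    }) |>
    dplyr::ungroup()
  if (p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out$stars <- p_stars(out$p_value)
  out
}

#' Bar plot of a per-marker summary
#'
#' Target and control means with SD error bars and significance stars, one
#' facet per marker.
#'
#' @param summary tibble from [summarize_markers()].
#' @return A ggplot.
#' @export
plot_marker_summary <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(cols = c("target_mean", "control_mean"),
                        names_to = "region", values_to = "mean") |>
    dplyr::mutate(region = sub("_mean", "", .data$region),
                  sd = ifelse(.data$region == "target", .data$target_sd,
                              .data$control_sd))
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$mean,
                                     fill = .data$region)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_text(data = summary,
                       ggplot2::aes(x = 1.5, y = Inf, label = .data$stars),
                       vjust = 1.5, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SD") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
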