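# Stiffness Asymmetry Index and group-level statistics.
#
# SAI = 1 - (AVF_F0 / AVF) / (NAVF_F0 / NAVF)
#
# where AVF / NAVF are the pixel areas of the affected / non-affected vocal
# fold and AVF_F0 / NAVF_F0 the vibrating pixel counts within them. 0 means
# symmetric vibration; values towards 1 mean the affected fold barely
# vibrates relative to the healthy one (e.g. 0.75 = high asymmetry).

#' Compute the Stiffness Asymmetry Index
#'
#' Vibrating fractions are computed per fold from the masks. With
#' `affected_side = "auto"` the fold with the smaller vibrating fraction is
#' taken as affected, which guarantees `sai` in `[0, 1]`; with a declared
#' side (the clinically known unilateral lesion side) `sai` can come out
#' negative, which is flagged as sign-inverted (the declared side vibrates
#' *better* than the healthy one). A non-affected fold that does not
#' vibrate at all (`NAVF_F0 = 0`) makes the index undefined and raises a
#' degenerate-input error: the index presumes unilateral disease.
#'
#' @param left_mask,right_mask disjoint, non-empty logical fold masks.
#' @param vibrating_mask logical mask of vibrating pixels, subset of the
#'   fold masks' union.
#' @param affected_side `"left"`, `"right"` or `"auto"`.
#' @return Object of class `sai_result`: `AVF`, `AVF_F0`, `NAVF`,
#'   `NAVF_F0`, `sai`, `affected_side` (resolved), `auto_resolved`,
#'   `sign_inverted`.
#' @export
compute_sai <- function(left_mask, right_mask, vibrating_mask,
                        affected_side = c("auto", "left", "right")) {
  affected_side <- match.arg(affected_side)
  if (any(left_mask & right_mask))
    ltg_input_error("fold masks must be disjoint")
  if (!any(left_mask) || !any(right_mask))
    ltg_input_error("fold masks must be non-empty")
  if (any(vibrating_mask & !(left_mask | right_mask)))
    ltg_input_error("vibrating mask must be a subset of the fold masks")

  n_l <- sum(left_mask);  v_l <- sum(vibrating_mask & left_mask)
  n_r <- sum(right_mask); v_r <- sum(vibrating_mask & right_mask)
  frac_l <- v_l / n_l; frac_r <- v_r / n_r

  auto <- affected_side == "auto"
  if (auto)  # smaller vibrating fraction = stiffer = affected; tie -> left
    affected_side <- if (frac_r < frac_l) "right" else "left"
  if (affected_side == "left") {
    AVF <- n_l; AVF_F0 <- v_l; NAVF <- n_r; NAVF_F0 <- v_r
  } else {
    AVF <- n_r; AVF_F0 <- v_r; NAVF <- n_l; NAVF_F0 <- v_l
  }
  if (NAVF_F0 == 0)
    ltg_degenerate_error(
      "non-affected fold shows no vibration: SAI undefined (bilateral stiffness?)")
  sai <- 1 - (AVF_F0 / AVF) / (NAVF_F0 / NAVF)
  structure(list(AVF = AVF, AVF_F0 = AVF_F0, NAVF = NAVF, NAVF_F0 = NAVF_F0,
                 sai = sai, affected_side = affected_side,
                 auto_resolved = auto, sign_inverted = sai < 0),
            class = "sai_result")
}

#' @export
print.sai_result <- function(x, ...) {
  cat(sprintf(
    "<sai_result> SAI = %.2f (affected: %s%s)\n  affected fold: %d / %d px vibrating; non-affected: %d / %d px\n",
    x$sai, x$affected_side, if (x$auto_resolved) ", auto" else "",
    x$AVF_F0, x$AVF, x$NAVF_F0, x$NAVF))
  if (x$sign_inverted)
    cat("  note: sign-inverted (declared affected fold vibrates better)\n")
  invisible(x)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments,
# valid with ties (midranks). Feasible for small pooled sizes only.
mw_exact_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))  # midranks
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  us <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Two-sided Mann-Whitney p: exact distribution for small samples (via
# wilcox.test when untied, full enumeration when tied and the pooled size
# permits), tie-corrected normal approximation otherwise.
mw_p_value <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && length(x) < 50 && length(y) < 50)
    return(stats::wilcox.test(x, y, alternative = "two.sided",
                              exact = TRUE)$p.value)
  if (ties && length(x) + length(y) <= 18L)
    return(mw_exact_enum_p(x, y))
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                      exact = FALSE))$p.value
}

#' Compare SAI distributions between subject groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests for every group pair,
#' using the exact null distribution in the small-sample study regime
#' (n <= 20 per group): [stats::wilcox.test()]'s exact path for untied
#' data, full enumeration of group assignments with midranks when ties are
#' present and the pooled size permits, and the tie-corrected normal
#' approximation otherwise. Per-group mean, SD, min and max are reported
#' alongside.
#'
#' @param results named list of numeric SAI vectors, one per group,
#'   each with at least 3 subjects; at least 2 groups.
#' @return Object of class `group_comparison`: `summary` (data frame:
#'   group, n, mean, sd, min, max), `tests` (data frame: group1, group2,
#'   p_value), `data` (the input).
#' @export
compare_groups <- function(results) {
  if (!is.list(results) || length(results) < 2L || is.null(names(results)))
    ltg_input_error("need a named list of at least 2 groups")
  sizes <- lengths(results)
  if (any(sizes < 3L))
    ltg_input_error("every group needs at least 3 subjects")
  summary <- data.frame(
    group = names(results), n = as.integer(sizes),
    mean = vapply(results, mean, 0), sd = vapply(results, stats::sd, 0),
    min = vapply(results, min, 0), max = vapply(results, max, 0),
    row.names = NULL)
  pairs <- utils::combn(names(results), 2)
  tests <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_value = apply(pairs, 2, function(p)
      mw_p_value(results[[p[1]]], results[[p[2]]])))
  structure(list(summary = summary, tests = tests, data = results),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s n=%2d  SAI %.2f +/- %.2f (%.2f-%.2f)\n",
                s$group[i], s$n[i], s$mean[i], s$sd[i], s$min[i], s$max[i]))
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("  %s vs %s: p = %.4f\n", x$tests$group1[i],
                x$tests$group2[i], x$tests$p_value[i]))
  invisible(x)
}

#' Box plot of SAI by group
#'
#' @param comparison a [compare_groups()] result.
#' @param file PNG output path, or `NULL` to draw on the current device.
#' @return `file`, invisibly.
#' @export
plot_sai_groups <- function(comparison, file = NULL) {
  stopifnot(inherits(comparison, "group_comparison"))
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 450)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(comparison$data, ylab = "SAI",
                    main = "Stiffness Asymmetry Index by group",
                    col = c("steelblue", "orange", "grey70"))
  invisible(file)
}
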