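# Percentile-bootstrap median comparisons.
#
# The fatigue indices are markedly skewed across subjects, so group
# contrasts are made on medians. Both tests are percentile bootstraps: the
# bootstrap distribution of the median contrast is computed by resampling
# within groups (or over within-subject differences when paired), and the
# two-sided p-value is twice the smaller tail probability of that
# distribution relative to zero.

col_medians <- function(m) {
  n <- nrow(m)
  sm <- apply(m, 2, sort.int, method = "quick")
  if (n %% 2 == 1) sm[(n + 1) / 2, ] else (sm[n / 2, ] + sm[n / 2 + 1, ]) / 2
}

boot_median <- function(x, n_boot) {
  n <- length(x)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  col_medians(matrix(x[idx], n, n_boot))
}

pboot_p <- function(stat_boot) {
  phat <- mean(stat_boot < 0) + 0.5 * mean(stat_boot == 0)
  min(1, 2 * min(phat, 1 - phat))
}

grp_summary <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(n = length(x), median = q[2], q25 = q[1], q75 = q[3])
}

#' One-way percentile-bootstrap median test
#'
#' Tests whether two groups differ in median. Paired (the default usage
#' for concentric vs eccentric, where each subject contributes both
#' phases): the within-subject differences are resampled and the bootstrap
#' distribution of their median is compared against zero. Unpaired: each
#' group is resampled independently and the difference of group medians is
#' bootstrapped.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired logical.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed; required for reproducible p-values.
#' @return object of class `median_test`: `statistic` (observed median
#'   difference), `p_value`, `groups` (per-group n/median/quartiles),
#'   `method` descriptor.
#' @export
median_test_oneway <- function(a, b, paired = TRUE, n_boot = 2000,
                               seed = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (paired && length(a) != length(b))
    stop("paired test requires equal-length samples")
  if (length(a) < 5 || length(b) < 5)
    stop("need at least 5 observations per group")
  if (!is.null(seed)) set.seed(seed)
  if (paired) {
    d <- a - b
    stat <- median(d)
    boot <- boot_median(d, n_boot)
  } else {
    stat <- median(a) - median(b)
    boot <- boot_median(a, n_boot) - boot_median(b, n_boot)
  }
  p <- if (all(boot == boot[1])) {
    if (boot[1] == 0) 1 else 0       # zero variance: degenerate bootstrap
  } else pboot_p(boot)
  groups <- rbind(grp_summary(a), grp_summary(b))
  groups$group <- c("a", "b")
  structure(list(statistic = stat, p_value = p, groups = groups,
                 method = list(type = "percentile-bootstrap median test",
                               paired = paired, n_boot = n_boot,
                               seed = seed)),
            class = "median_test")
}

#' Two-way percentile-bootstrap median test
#'
#' Tests main effects and interaction of two two-level factors (here:
#' age group x gender) on cell medians. Effects are contrasts of the 2 x 2
#' cell medians: main effects are differences of marginal means of cell
#' medians, the interaction is the difference of differences. Cells are
#' resampled independently.
#'
#' @param values numeric observations.
#' @param factor_a,factor_b two-level factors (coerced), same length as
#'   `values`.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param min_cell minimum observations per cell.
#' @return list of class `median_test_twoway` with elements `a`, `b`,
#'   `interaction` (each a `median_test`-like list) and `cells` (cell
#'   summaries).
#' @export
median_test_twoway <- function(values, factor_a, factor_b, n_boot = 2000,
                               seed = NULL, min_cell = 5) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) != 2 || nlevels(fb) != 2)
    stop("both factors must have exactly two levels")
  ok <- is.finite(values)
  values <- values[ok]; fa <- fa[ok]; fb <- fb[ok]
  cells <- split(values, list(fa, fb), sep = ":")
  if (any(lengths(cells) < min_cell))
    stop("each of the four cells needs at least ", min_cell, " observations")
  if (!is.null(seed)) set.seed(seed)
  cm <- vapply(cells, median, numeric(1))           # a1:b1 a2:b1 a1:b2 a2:b2
  boots <- lapply(cells, boot_median, n_boot = n_boot)
  eff <- function(m11, m21, m12, m22)
    list(a = (m11 + m12) / 2 - (m21 + m22) / 2,
         b = (m11 + m21) / 2 - (m12 + m22) / 2,
         interaction = (m11 - m12) - (m21 - m22))
  obs <- eff(cm[1], cm[2], cm[3], cm[4])
  bt <- eff(boots[[1]], boots[[2]], boots[[3]], boots[[4]])
  mk <- function(name) {
    b <- bt[[name]]
    p <- if (all(b == b[1])) { if (b[1] == 0) 1 else 0 } else pboot_p(b)
    list(effect = name, statistic = unname(obs[[name]]), p_value = p)
  }
  cell_tab <- do.call(rbind, lapply(names(cells), function(nm) {
    g <- grp_summary(cells[[nm]]); g$cell <- nm; g
  }))
  structure(list(a = mk("a"), b = mk("b"), interaction = mk("interaction"),
                 cells = cell_tab,
                 method = list(type = "percentile-bootstrap two-way median test",
                               n_boot = n_boot, seed = seed)),
            class = "median_test_twoway")
}

#' Cohort report table of fatigue indices
#'
#' For each parameter (normalized RMS / IMDF, initial value / normalized
#' slope) and reporting row (all electrodes, L5, L2, L1, most negative
#' electrode): cohort medians and quartiles of the concentric and the
#' eccentric value, and the paired one-way bootstrap median test between
#' phases.
#'
#' @param summaries list of `subject_summary` objects ([aggregate_subject()]).
#' @param n_boot,seed bootstrap settings.
#' @return data.frame, one row per parameter x quantity x reporting row.
#' @export
cohort_table <- function(summaries, n_boot = 2000, seed = 1L) {
  if (length(summaries) < 2) stop("need at least 2 subjects")
  all_rows <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    r <- summaries[[i]]$rows; r$subject <- i; r
  }))
  out <- list()
  test_seed <- seed
  for (par in unique(all_rows$parameter)) {
    for (qty in c("initial_value", "normalized_slope")) {
      for (rw in c("all", "L5", "L2", "L1", "most_negative")) {
        sel <- all_rows[all_rows$parameter == par & all_rows$row == rw, ]
        co <- sel[sel$phase == "concentric", ]
        ec <- sel[sel$phase == "eccentric", ]
        co <- co[order(co$subject), ][[qty]]
        ec <- ec[order(ec$subject), ][[qty]]
        # with fewer than 5 subjects the bootstrap test is not meaningful;
        # report the median difference with a missing p-value
        tst <- if (length(co) >= 5)
          median_test_oneway(co, ec, paired = TRUE, n_boot = n_boot,
                             seed = test_seed)
        else list(statistic = median(co - ec), p_value = NA_real_)
        test_seed <- test_seed + 1L
        qc <- quantile(co, c(0.25, 0.5, 0.75), names = FALSE)
        qe <- quantile(ec, c(0.25, 0.5, 0.75), names = FALSE)
        out[[length(out) + 1]] <- data.frame(
          parameter = par, quantity = qty, row = rw,
          conc_median = qc[2], conc_q25 = qc[1], conc_q75 = qc[3],
          ecc_median = qe[2], ecc_q25 = qe[1], ecc_q75 = qe[3],
          statistic = tst$statistic, p_value = tst$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort table of concentric/eccentric ratios with age x gender tests
#'
#' Mirrors the ratio analysis: per parameter and reporting row, the cohort
#' median (quartiles) of the per-subject concentric/eccentric ratio of
#' initial values and of slopes, with two-way bootstrap median tests for
#' age group (binned at the cohort median age by default) and gender.
#'
#' @param summaries list of `subject_summary`.
#' @param age,sex per-subject vectors aligned with `summaries`.
#' @param age_cut age cut-off in years; default the cohort median.
#' @param n_boot,seed bootstrap settings.
#' @return data.frame, one row per parameter x ratio kind x reporting row,
#'   with effect statistics and p-values for age, gender, interaction.
#' @export
cohort_ratio_table <- function(summaries, age, sex, age_cut = NULL,
                               n_boot = 2000, seed = 1L) {
  if (is.null(age_cut)) age_cut <- median(age)
  age_grp <- ifelse(age <= age_cut, "younger", "older")
  ratios <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    r <- summaries[[i]]$ratios; r$subject <- i; r
  }))
  out <- list()
  test_seed <- seed
  for (par in unique(ratios$parameter)) {
    for (qty in c("initial_ratio", "slope_ratio")) {
      for (rw in c("all", "L5", "L2", "L1", "most_negative")) {
        sel <- ratios[ratios$parameter == par & ratios$row == rw, ]
        sel <- sel[order(sel$subject), ]
        v <- sel[[qty]]
        q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
        tw <- median_test_twoway(v, age_grp[sel$subject], sex[sel$subject],
                                 n_boot = n_boot, seed = test_seed)
        test_seed <- test_seed + 1L
        out[[length(out) + 1]] <- data.frame(
          parameter = par, quantity = qty, row = rw,
          median = q[2], q25 = q[1], q75 = q[3],
          age_stat = tw$a$statistic, age_p = tw$a$p_value,
          gender_stat = tw$b$statistic, gender_p = tw$b$p_value,
          interaction_stat = tw$interaction$statistic,
          interaction_p = tw$interaction$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
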