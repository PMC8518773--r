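# Plot-level statistics: the correlation ratio (eta^2) of soil properties
# against terrain-attribute terciles, tercile summary tables, and
# Kruskal-Wallis with Dunn's post hoc comparisons.

#' Min-max tercile binning of a terrain attribute
#'
#' Values are standardized to `[0, 1]` with their minimum and maximum and cut
#' at 1/3 and 2/3 into low / medium / high. Bins are left-closed; the maximum
#' maps to H.
#'
#' @param values Numeric vector (>= 3 values, max > min).
#' @return List of class `bc_terciles`: `labels` (factor L/M/H), `min`, `max`.
#' @export
tercile_bins <- function(values) {
  v <- values
  keep <- !is.na(v)
  if (sum(keep) < 3) stop("need at least 3 values")
  lo <- min(v[keep]); hi <- max(v[keep])
  if (hi <= lo) stop("constant values: tercile standardization undefined")
  vhat <- (v - lo) / (hi - lo)
  lab <- ifelse(vhat < 1 / 3, "L", ifelse(vhat < 2 / 3, "M", "H"))
  structure(list(labels = factor(lab, levels = c("L", "M", "H")),
                 min = lo, max = hi),
            class = "bc_terciles")
}

#' Correlation ratio (eta squared)
#'
#' Count-weighted between-category variance of `y` over its total variance:
#' `eta^2 = sum_x n_x (mean_x - mean)^2 / sum_i (y_i - mean)^2`, in `[0, 1]`.
#'
#' @param y Numeric response (a soil property).
#' @param labels Category labels (a terrain-attribute tercile per plot).
#' @return `eta^2`.
#' @export
correlation_ratio <- function(y, labels) {
  keep <- !is.na(y) & !is.na(labels)
  y <- y[keep]; labels <- droplevels(factor(labels[keep]))
  if (nlevels(labels) < 2) stop("need at least 2 non-empty categories")
  tot <- sum((y - mean(y))^2)
  if (tot == 0) stop("zero total variance in y")
  means <- tapply(y, labels, mean)
  ns <- tapply(y, labels, length)
  sum(ns * (means - mean(y))^2) / tot
}

#' Tercile summary table of soil properties by terrain attributes
#'
#' For each terrain attribute x soil property pair: mean and s.d. of the
#' property within each min-max tercile of the attribute, plus eta^2.
#' Rows with `eta^2 < eta2_min` are flagged `represented = FALSE` (weakly
#' explained pairs are conventionally left out of the printed table).
#'
#' @param plots Data frame of per-plot values.
#' @param attributes Names of terrain-attribute columns in `plots`.
#' @param properties Names of soil-property columns in `plots`.
#' @param eta2_min Representation threshold on eta^2 (default 0.3).
#' @return Data frame with one row per attribute x property.
#' @export
tercile_table <- function(plots, attributes, properties, eta2_min = 0.3) {
  rows <- list()
  for (a in attributes) {
    bins <- tercile_bins(plots[[a]])
    for (p in properties) {
      y <- plots[[p]]
      e2 <- correlation_ratio(y, bins$labels)
      m <- tapply(y, bins$labels, mean)
      s <- tapply(y, bins$labels, stats::sd)
      rows[[length(rows) + 1]] <- data.frame(
        attribute = a, property = p,
        L_mean = m[["L"]], L_sd = s[["L"]],
        M_mean = m[["M"]], M_sd = s[["M"]],
        H_mean = m[["H"]], H_sd = s[["H"]],
        eta2 = e2, represented = e2 >= eta2_min)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# tie-corrected Dunn z statistic machinery
dunn_z <- function(ranks, groups) {
  n <- length(ranks)
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(ranks, groups, mean)
  ns <- tapply(ranks, groups, length)
  lev <- names(rbar)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    if (se == 0) return(0)
    (rbar[[i]] - rbar[[j]]) / se
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z))
}

# compact letter display: groups sharing a letter are not significantly
# different (insert-absorb over the pairwise significance matrix)
cld_letters <- function(levels_, sig_pairs) {
  sets <- list(levels_)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[k]; b <- sig_pairs$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets))
      if (i != j && keep[i] && all(new_sets[[i]] %in% new_sets[[j]]) &&
          length(new_sets[[i]]) < length(new_sets[[j]])) keep[i] <- FALSE
    sets <- unique(new_sets[keep])
  }
  out <- stats::setNames(rep("", length(levels_)), levels_)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[[g]] <- paste0(out[[g]], letters[i])
  out
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' The omnibus Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's pairwise z tests on mean ranks with tie-corrected
#' variance; pairwise p-values are two-sided and adjusted by `adjust`
#' (default Holm). Compact letter display groups levels that do not differ at
#' `alpha`.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param adjust Method for [stats::p.adjust()].
#' @param alpha Significance level for the letter display.
#' @return List of class `bc_kruskal_dunn`: `kw_h`, `kw_p`, `pairwise`
#'   (group1, group2, z, p, p_adjusted), `letters`.
#' @export
kruskal_dunn <- function(values, groups, adjust = "holm", alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) < 2)
    stop("all values identical: no ranking information")
  kw <- stats::kruskal.test(values, groups)
  ranks <- rank(values)
  pw <- dunn_z(ranks, groups)
  pw$p <- 2 * stats::pnorm(-abs(pw$z))
  pw$p_adjusted <- stats::p.adjust(pw$p, method = adjust)
  sig <- pw[pw$p_adjusted < alpha, c("group1", "group2")]
  lets <- cld_letters(levels(groups), sig)
  structure(list(kw_h = unname(kw$statistic), kw_p = kw$p.value,
                 pairwise = pw, letters = lets),
            class = "bc_kruskal_dunn")
}

#' @export
print.bc_kruskal_dunn <- function(x, ...) {
  cat("Kruskal-Wallis H =", signif(x$kw_h, 5), ", p =", signif(x$kw_p, 4), "\n")
  print(x$pairwise, row.names = FALSE)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}
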