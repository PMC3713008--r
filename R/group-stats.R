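# The statistical battery: one-way ANOVA gate, pairwise Wilcoxon rank-sum
# tests, Benjamini-Hochberg correction, and significance-count summaries.

#' One-way ANOVA gate across the three tissue classes
#'
#' Fixed-effects one-way ANOVA F-test p-value across the groups. The texture
#' parameters are not normally distributed; the ANOVA is used only as a
#' liberal gate before the nonparametric pairwise tests, not as the inferential
#' result.
#'
#' @param groups List of numeric vectors (one per tissue class); each needs
#'   at least 2 finite values, otherwise the gate is undetermined (`NA`).
#' @return The F-test p-value, or `NA_real_` when undetermined.
#' @examples
#' anova_gate(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))  # F = 0 -> p = 1
#' @export
anova_gate <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, integer(1)) < 2L)) return(NA_real_)
  values <- unlist(groups, use.names = FALSE)
  cls <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  grand <- mean(values)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ss_between <= .Machine$double.eps * max(1, sum(values^2))) return(1)
  if (ss_within <= 0) return(0)
  stats::oneway.test(values ~ cls, var.equal = TRUE)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param mode `"exact"` enumerates all `choose(n + m, n)` group assignments
#'   of the mid-ranks (permutation-exact even under ties) and is limited to
#'   `n + m <= 12`; `"normal_approx"` uses the normal approximation with
#'   tie-corrected variance and continuity correction; `"auto"` (default)
#'   picks exact when feasible and there are no ties.
#' @return Two-sided p-value. Degenerate input (all values identical across
#'   both groups) gives `p = 1`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (diff(range(pooled)) == 0) return(1)
  ties <- anyDuplicated(pooled) > 0L
  if (mode == "auto")
    mode <- if (na + nb <= 12L && !ties) "exact" else "normal_approx"
  if (mode == "exact") {
    if (na + nb > 12L)
      stop("exact mode limited to n + m <= 12; use mode = 'normal_approx'")
    r <- rank(pooled)  # mid-ranks; under ties this is the permutation-exact test
    w_obs <- sum(r[seq_len(na)])
    combos <- combn(na + nb, na)
    w_all <- colSums(matrix(r[combos], nrow = na))
    tol <- 1e-9
    p_lo <- mean(w_all <= w_obs + tol)
    p_hi <- mean(w_all >= w_obs - tol)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  res$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false discovery rate control: with p-values sorted ascending,
#' `adj_(i) = min over j >= i of min(1, m * p_(j) / j)`, restored to the
#' input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @param m Family size (defaults to the number of non-`NA` p-values).
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(pvals, m = NULL) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  k <- length(p)
  m <- m %||% k
  if (m < k) stop("family size `m` cannot be smaller than the number of p-values")
  out <- rep(NA_real_, length(pvals))
  if (k > 0L) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (k:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Run the full ANOVA-gated Wilcoxon battery over the record grid
#'
#' For every (texture map, statistic, interval) cell of the record grid the
#' records are grouped by tissue class; a one-way ANOVA gate at `gate_alpha`
#' decides whether the three pairwise Wilcoxon rank-sum tests
#' (NAWM vs EL, NAWM vs NEL, NEL vs EL) are performed; their p-values are
#' Benjamini-Hochberg adjusted within the configured scope and compared
#' against `alpha`. Undetermined records are excluded; cells whose gate
#' cannot be evaluated are reported as skipped.
#'
#' @param records Record tibble from [extract_toi_records()].
#' @param gate_alpha ANOVA gate level (default 0.05). Set to 1 to disable
#'   gating (all pairwise tests performed).
#' @param alpha Significance level for the adjusted pairwise p-values.
#' @param bh_scope Family for the BH adjustment: `"per_cell"` (the three
#'   pairwise tests of one cell, default — the smallest family consistent
#'   with reporting three adjusted columns per cell), `"per_tpm"` (all
#'   pairwise tests of one texture map) or `"global"`.
#' @param wilcox_mode Passed to [wilcoxon_rank_sum()].
#' @return A tibble of class `dtpa_battery`, one row per cell, with columns
#'   `tpm_type`, `statistic`, `interval`, group sizes, `anova_p`, `gated`,
#'   raw and adjusted p-values per pair (`p_*`, `q_*`), and `n_significant`.
#'   Attributes `alpha`, `gate_alpha`, `bh_scope` record the configuration.
#' @export
run_full_battery <- function(records, gate_alpha = 0.05, alpha = 0.05,
                             bh_scope = c("per_cell", "per_tpm", "global"),
                             wilcox_mode = "auto") {
  bh_scope <- match.arg(bh_scope)
  rec <- records[!records$undetermined & is.finite(records$value), ]
  key <- interaction(rec$tpm_type, rec$statistic, rec$interval, drop = TRUE)
  cells <- split(rec, key)
  pair_def <- list(NAWM_vs_EL = c("NAWM", "EL"),
                   NAWM_vs_NEL = c("NAWM", "NEL"),
                   NEL_vs_EL = c("NEL", "EL"))
  rows <- lapply(cells, function(cell) {
    g <- split(cell$value, factor(as.character(cell$tissue_class),
                                  levels = c("NAWM", "EL", "NEL")))
    p_anova <- anova_gate(g)
    gated <- !is.na(p_anova) && p_anova < gate_alpha
    praw <- setNames(rep(NA_real_, 3L), names(pair_def))
    if (gated) {
      for (pn in names(pair_def)) {
        x <- g[[pair_def[[pn]][1]]]; y <- g[[pair_def[[pn]][2]]]
        if (length(x) >= 1L && length(y) >= 1L)
          praw[pn] <- wilcoxon_rank_sum(x, y, mode = wilcox_mode)
      }
    }
    tibble::tibble(
      tpm_type = cell$tpm_type[1], statistic = cell$statistic[1],
      interval = cell$interval[1],
      n_NAWM = length(g$NAWM), n_EL = length(g$EL), n_NEL = length(g$NEL),
      anova_p = p_anova, gated = gated,
      p_NAWM_vs_EL = praw[1], p_NAWM_vs_NEL = praw[2], p_NEL_vs_EL = praw[3])
  })
  res <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$tpm_type, .data$statistic, .data$interval)
  pcols <- paste0("p_", TISSUE_PAIRS)
  qcols <- paste0("q_", TISSUE_PAIRS)
  P <- as.matrix(res[, pcols])
  Q <- matrix(NA_real_, nrow(P), 3L, dimnames = list(NULL, qcols))
  if (bh_scope == "per_cell") {
    for (i in seq_len(nrow(P))) Q[i, ] <- bh_adjust(P[i, ])
  } else {
    fam <- if (bh_scope == "global") rep(1L, nrow(P)) else as.integer(res$tpm_type)
    for (f in unique(fam)) {
      sel <- fam == f
      Q[sel, ] <- matrix(bh_adjust(as.vector(P[sel, , drop = FALSE])), ncol = 3L)
    }
  }
  res <- dplyr::bind_cols(res, tibble::as_tibble(Q))
  res$n_significant <- rowSums(Q < alpha, na.rm = TRUE)
  structure(res, class = c("dtpa_battery", class(res)),
            alpha = alpha, gate_alpha = gate_alpha, bh_scope = bh_scope)
}

#' Significance-count summary of a battery
#'
#' Cross-tabulates the number of significant pairwise tests by texture map
#' and interval (with row and column totals) and reports the number of
#' possible pairwise tests together with the count of false positives
#' expected at level `alpha` if no real differences existed
#' (`n_tests_possible * alpha`) — the yardstick against which the observed
#' total is judged.
#'
#' @param results A `dtpa_battery` from [run_full_battery()].
#' @param alpha Significance level (defaults to the battery's).
#' @return A tibble of class `dtpa_counts` (rows = texture maps + `Total`,
#'   columns = intervals + `Total`) with attributes `n_tests_possible` and
#'   `expected_false_positives`.
#' @export
summarize_counts <- function(results, alpha = NULL) {
  stopifnot(inherits(results, "dtpa_battery"))
  alpha <- alpha %||% attr(results, "alpha")
  qcols <- paste0("q_", TISSUE_PAIRS)
  Q <- as.matrix(results[, qcols])
  sig <- rowSums(Q < alpha, na.rm = TRUE)
  tab <- tapply(sig, list(factor(as.character(results$tpm_type), levels = TPM_TYPES),
                          factor(as.character(results$interval), levels = INTERVALS)),
                sum, default = 0L)
  tab <- cbind(tab, Total = rowSums(tab))
  tab <- rbind(tab, Total = colSums(tab))
  n_possible <- 3L * nrow(results)
  out <- tibble::as_tibble(tab, rownames = "tpm_type")
  structure(out, class = c("dtpa_counts", class(out)),
            alpha = alpha,
            n_tests_possible = n_possible,
            expected_false_positives = n_possible * alpha)
}

#' @export
print.dtpa_counts <- function(x, ...) {
  cat("Significant pairwise tests per texture map and interval\n")
  NextMethod()
  cat(sprintf("possible tests: %d; expected false positives at alpha = %g: %.6g\n",
              attr(x, "n_tests_possible"), attr(x, "alpha"),
              attr(x, "expected_false_positives")))
  invisible(x)
}
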