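#' Covariate-adjusted one-sided two-group comparison
#'
#' Linear regression of a nodal value on a group indicator plus age and sex,
#' with a one-sided p-value for the hypothesis that the first group's
#' adjusted mean exceeds the second's. Pooled-variance inference via the
#' regression t statistic.
#'
#' @param values Numeric vector, one value per subject (both groups).
#' @param group Factor/character of group membership per subject.
#' @param first,second Labels of the two groups; the alternative is
#'   `first > second`.
#' @param covariates Data frame with rows matching `values` (typically
#'   columns `age`, `sex`), or NULL for an unadjusted test.
#' @return List with `t` (statistic), `p` (one-sided p-value), `df`.
#' @export
adjusted_one_sided_test <- function(values, group, first, second,
                                    covariates = NULL) {
  sel <- group %in% c(first, second)
  v <- values[sel]
  g <- as.numeric(group[sel] == first)
  if (sum(g) < 3 || sum(1 - g) < 3)
    stopf("need at least 3 subjects per group (%s: %d, %s: %d)",
          first, sum(g), second, sum(1 - g))
  X <- cbind(1, indicator = g)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates[sel, , drop = FALSE])
    ok <- apply(cv, 2, function(col) stats::sd(col) > 0)
    if (!all(ok)) cv <- cv[, ok, drop = FALSE]
    if (ncol(cv)) X <- cbind(X, cv)
  }
  XtX <- crossprod(X)
  beta <- tryCatch(solve(XtX, crossprod(X, v)),
                   error = function(e) NULL)
  df <- length(v) - ncol(X)
  if (is.null(beta) || df < 1) stopf("singular design in group comparison")
  resid <- v - X %*% beta
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * solve(XtX)[2, 2])
  if (!is.finite(se) || se == 0) stopf("singular design in group comparison")
  t <- beta[2] / se
  list(t = unname(t), p = stats::pt(t, df, lower.tail = FALSE), df = df)
}

#' Benjamini-Hochberg significance calls
#'
#' Step-up FDR over a vector of p-values; a hypothesis is called significant
#' when its BH-adjusted p-value is below `alpha` (the strict inequality
#' mirrors the "p < 0.05, FDR corrected" convention used throughout).
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param alpha FDR level.
#' @return Logical vector.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  stats::p.adjust(pvals, method = "BH") < alpha
}

# The six ordered comparisons spanning four groups.
six_comparisons <- function() {
  list(c("NC", "EMCI"), c("NC", "LMCI"), c("NC", "AD"),
       c("EMCI", "LMCI"), c("EMCI", "AD"), c("LMCI", "AD"))
}

#' Nodes whose measure declines progressively across the four groups
#'
#' Runs six one-sided covariate-adjusted comparisons (NC > EMCI, NC > LMCI,
#' NC > AD, EMCI > LMCI, EMCI > AD, LMCI > AD) per node, applies
#' Benjamini-Hochberg across nodes within each comparison, and intersects
#' the six significant sets: a node qualifies only if it is significant in
#' every comparison.
#'
#' @param measures Subjects x nodes numeric matrix (one nodal measure).
#' @param cohort Cohort manifest with columns `group`, `age`, `sex`, rows
#'   aligned with `measures`.
#' @param measure_name Label carried into the report (e.g. "MP" or "BC").
#' @param alpha FDR level per comparison.
#' @param adjust Adjust for age and sex (TRUE) or run unadjusted tests.
#' @return An object of class `progressive_report`: `measure_name`,
#'   `common_nodes` (character), `per_comparison` (list of data frames with
#'   node, t, p, q, significant).
#' @export
progressive_nodes <- function(measures, cohort, measure_name = "MP",
                              alpha = 0.05, adjust = TRUE) {
  measures <- as.matrix(measures)
  stopifnot(nrow(measures) == nrow(cohort))
  if (!all(c("NC", "EMCI", "LMCI", "AD") %in% as.character(cohort$group)))
    stopf("all four groups (NC, EMCI, LMCI, AD) must be present")
  nodes <- colnames(measures) %||% paste0("V", seq_len(ncol(measures)))
  covs <- if (adjust) cohort[, c("age", "sex")] else NULL
  per <- lapply(six_comparisons(), function(cmp) {
    res <- lapply(seq_len(ncol(measures)), function(j) {
      tryCatch(
        adjusted_one_sided_test(measures[, j], cohort$group, cmp[1], cmp[2], covs),
        error = function(e) list(t = NA_real_, p = NA_real_, df = NA_real_))
    })
    p <- vapply(res, `[[`, numeric(1), "p")
    sig <- fdr_bh(p, alpha)
    sig[is.na(sig)] <- FALSE  # untestable nodes (degenerate design) never qualify
    data.frame(node = nodes,
               t = vapply(res, `[[`, numeric(1), "t"),
               p = p,
               q = stats::p.adjust(p, method = "BH"),
               significant = sig,
               stringsAsFactors = FALSE)
    })
  names(per) <- vapply(six_comparisons(), function(cmp)
    paste0(cmp[1], ">", cmp[2]), character(1))
  sig_sets <- lapply(per, function(df) df$node[df$significant])
  common <- Reduce(intersect, sig_sets)
  structure(list(measure_name = measure_name, common_nodes = common,
                 per_comparison = per, alpha = alpha, adjusted = adjust),
            class = "progressive_report")
}

#' @export
print.progressive_report <- function(x, ...) {
  cat(sprintf("Progressive-decline report for %s (alpha = %g%s)\n",
              x$measure_name, x$alpha,
              if (x$adjusted) ", age/sex adjusted" else ""))
  for (nm in names(x$per_comparison)) {
    cat(sprintf("  %-10s %3d significant nodes\n", nm,
                sum(x$per_comparison[[nm]]$significant)))
  }
  cat(sprintf("  common nodes: %s\n",
              if (length(x$common_nodes)) paste(x$common_nodes, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Pearson correlation of a nodal measure with a behavioral score
#'
#' @param values Numeric vector (nodal measure per subject).
#' @param scores Numeric vector (behavioral score per subject).
#' @return List with `r` and two-sided `p`.
#' @export
behavioral_correlation <- function(values, scores) {
  stopifnot(length(values) == length(scores))
  if (length(values) < 4) stopf("need at least 4 paired observations")
  if (stats::sd(values) == 0 || stats::sd(scores) == 0)
    stopf("zero-variance input: correlation undefined")
  ct <- stats::cor.test(values, scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Undirected functional-connectivity network for one subject
#'
#' Pearson correlation between every pair of ROI series, per-connection
#' p-values from the correlation t-test, Benjamini-Hochberg across the
#' unique pairs, binarized at `alpha`. The adjacency is symmetric.
#'
#' @param obs A [roi_timeseries()] or T x q matrix.
#' @param alpha FDR level for connection selection.
#' @return A [directed_network()] with symmetric adjacency.
#' @export
fc_network <- function(obs, alpha = 0.05) {
  Y <- as_matrix_series(obs)
  q <- ncol(Y)
  n <- nrow(Y)
  labels <- colnames(Y) %||% paste0("ROI", seq_len(q))
  R <- stats::cor(Y)
  ut <- upper.tri(R)
  r <- R[ut]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- fdr_bh(p, alpha)
  adj <- matrix(FALSE, q, q)
  adj[ut] <- sig
  adj <- adj | t(adj)
  directed_network(adj, labels)
}

#' Undirected-FC comparison arm
#'
#' The conventional-connectivity control analysis: per subject, an
#' FDR-binarized Pearson correlation network and its betweenness centrality
#' (computed on the symmetric adjacency treated as a digraph with reciprocal
#' edges), followed by the same six-comparison progressive analysis.
#' Middleman power is not defined for undirected networks and is not
#' computed.
#'
#' @param observed_list List of [roi_timeseries()], one per subject, aligned
#'   with `cohort` rows.
#' @param cohort Cohort manifest.
#' @param alpha_edge FDR level for connection selection.
#' @param alpha_group FDR level per group comparison.
#' @param adjust Adjust for age and sex.
#' @return A `progressive_report` for measure "BC_FC", with the per-subject
#'   BC matrix attached as attribute `bc`.
#' @export
fc_bc_comparison_arm <- function(observed_list, cohort, alpha_edge = 0.05,
                                 alpha_group = 0.05, adjust = TRUE) {
  stopifnot(length(observed_list) == nrow(cohort))
  bc <- t(vapply(observed_list, function(obs) {
    betweenness_directed(fc_network(obs, alpha_edge))
  }, numeric(ncol(as_matrix_series(observed_list[[1]])))))
  rep <- progressive_nodes(bc, cohort, measure_name = "BC_FC",
                           alpha = alpha_group, adjust = adjust)
  attr(rep, "bc") <- bc
  rep
}

#' Write a progressive report to disk
#'
#' One CSV per comparison (node, t, p, q, significant), a JSON file listing
#' the common nodes, and a plain-text summary.
#'
#' @param report A `progressive_report`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_progressive_report <- function(report, dir, prefix = report$measure_name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$per_comparison)) {
    fn <- file.path(dir, sprintf("%s_%s.csv", prefix, gsub(">", "_gt_", nm)))
    utils::write.csv(report$per_comparison[[nm]], fn, row.names = FALSE)
  }
  jsonlite::write_json(
    list(measure = report$measure_name, alpha = report$alpha,
         common_nodes = report$common_nodes),
    file.path(dir, sprintf("%s_common_nodes.json", prefix)),
    auto_unbox = TRUE, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, sprintf("%s_summary.txt", prefix)))
  invisible(dir)
}
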