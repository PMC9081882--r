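# Between-condition contrasts: total and node-level connectivity tests,
# hemispheric edge counts, positive-correlation fraction, and per-region
# density comparisons.  Every connectivity contrast reports both the
# unpaired Student t (pooled variance, df = n_a + n_b - 2) and the
# Kruskal-Wallis test on the same vectors; neither is privileged.

two_group_tests <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = TRUE)
  kw <- stats::kruskal.test(list(a, b))
  list(
    mean_a = mean(a), mean_b = mean(b),
    sem_a = stats::sd(a) / sqrt(length(a)),
    sem_b = stats::sd(b) / sqrt(length(b)),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_t = tt$p.value,
    H = unname(kw$statistic), p_kw = kw$p.value,
    n_a = length(a), n_b = length(b))
}

#' Total-connectivity contrast between two conditions
#'
#' Compares the all-pairs Fisher-z connectivity strengths of two condition
#' networks (435 values each for the default atlas): per-condition mean and
#' SEM, an unpaired two-sided Student t-test with
#' `df = n_a + n_b - 2` (868 for two full 30-region conditions), and the
#' Kruskal-Wallis test on the same vectors.
#'
#' @param z_a,z_b Numeric z-score vectors, e.g. from [all_pairs_z()].
#' @return List with `mean_a`, `mean_b`, `sem_a`, `sem_b`, `t`, `df`,
#'   `p_t`, `H`, `p_kw`, `n_a`, `n_b`.
#' @export
total_connectivity_contrast <- function(z_a, z_b) {
  if (length(z_a) < 2L || length(z_b) < 2L)
    stop("both z vectors must have length >= 2")
  two_group_tests(z_a, z_b)
}

#' Node-level connectivity contrast between two conditions
#'
#' Extracts one region's Fisher-z connectivity strengths to every other
#' region (29 values per condition for the default atlas, no significance
#' filter) and applies the same two tests as
#' [total_connectivity_contrast()].  Used for the locus coeruleus contrast.
#'
#' @param corr_a,corr_b `fos_corr` objects for the two conditions.
#' @param node Region code, e.g. `"LC-L"`.
#' @return As [total_connectivity_contrast()], plus `node`.
#' @export
node_connectivity_contrast <- function(corr_a, corr_b, node) {
  stopifnot(inherits(corr_a, "fos_corr"), inherits(corr_b, "fos_corr"))
  pull <- function(corr) {
    if (!node %in% rownames(corr$rho))
      stop("unknown region code: ", node)
    r <- corr$rho[node, ]
    r <- r[names(r) != node]
    r <- r[!is.na(r)]
    if (length(r) == 0L)
      stop("all correlations undefined for region ", node)
    fisher_z(r)
  }
  out <- two_group_tests(pull(corr_a), pull(corr_b))
  out$node <- node
  out
}

#' Hemispheric significant-edge counts per area group
#'
#' For each named area group (frontal, hippocampal, amygdalar, brainstem),
#' counts the significant edges of either sign with at least one endpoint
#' in the group, split into intra-left (both endpoints left hemisphere),
#' intra-right, and inter-hemisphere.  An edge joining two groups is
#' counted in both groups; regions with `area_group` "other" contribute
#' only through edges shared with a named group.
#'
#' @param net A `fos_network`.
#' @return Data frame with columns `area_group`, `intra_left`,
#'   `intra_right`, `inter`.
#' @export
hemispheric_counts <- function(net) {
  stopifnot(inherits(net, "fos_network"))
  atlas <- net$atlas
  groups <- c("frontal", "hippocampal", "amygdalar", "brainstem")
  grp <- stats::setNames(atlas$area_group, atlas$code)
  hemi <- stats::setNames(atlas$hemisphere, atlas$code)
  e <- net$edges
  out <- data.frame(area_group = groups, intra_left = 0L, intra_right = 0L,
                    inter = 0L, stringsAsFactors = FALSE)
  if (nrow(e) == 0L) return(out)
  g_from <- grp[e$from]; g_to <- grp[e$to]
  h_from <- hemi[e$from]; h_to <- hemi[e$to]
  for (k in seq_along(groups)) {
    in_g <- g_from == groups[k] | g_to == groups[k]
    out$intra_left[k] <- sum(in_g & h_from == "left" & h_to == "left")
    out$intra_right[k] <- sum(in_g & h_from == "right" & h_to == "right")
    out$inter[k] <- sum(in_g & h_from != h_to)
  }
  out
}

#' Fraction of positive correlations
#'
#' Share of defined region pairs with Spearman rho > 0.
#'
#' @param corr A `fos_corr`.
#' @return Fraction in \[0, 1\].
#' @export
positive_fraction <- function(corr) {
  stopifnot(inherits(corr, "fos_corr"))
  r <- corr$rho[upper.tri(corr$rho)]
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("no defined correlation pairs")
  mean(r > 0)
}

#' Per-region density contrast between two cohorts
#'
#' Two-group comparison of each region's c-Fos density across animals:
#' unpaired Student t-test and Mann-Whitney (Wilcoxon rank-sum) test,
#' uncorrected p-values by default with optional Benjamini-Hochberg
#' adjusted columns.
#'
#' @param cohort_a,cohort_b `fos_cohort` objects sharing an atlas.
#' @param adjust `"none"` (default) or `"BH"` to append adjusted columns.
#' @return Data frame, one row per region: `code`, `mean_a`, `mean_b`,
#'   `t`, `p_t`, `W`, `p_w` (and `p_t_adj`, `p_w_adj` when `adjust="BH"`).
#'   Regions with fewer than 2 non-missing animals in either cohort are
#'   flagged `NA` with a warning.
#' @export
regional_density_contrast <- function(cohort_a, cohort_b,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(cohort_a, "fos_cohort"), inherits(cohort_b, "fos_cohort"))
  if (!identical(cohort_a$atlas$code, cohort_b$atlas$code))
    stop("cohorts use different atlases")
  codes <- cohort_a$atlas$code
  res <- lapply(codes, function(cd) {
    a <- cohort_a$densities[, cd]; a <- a[!is.na(a)]
    b <- cohort_b$densities[, cd]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(code = cd, mean_a = NA_real_, mean_b = NA_real_,
                        t = NA_real_, p_t = NA_real_, W = NA_real_,
                        p_w = NA_real_, stringsAsFactors = FALSE))
    tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                   error = function(e) NULL)   # both groups constant
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    data.frame(code = cd, mean_a = mean(a), mean_b = mean(b),
               t = if (is.null(tt)) 0 else unname(tt$statistic),
               p_t = if (is.null(tt)) 1 else tt$p.value,
               W = unname(wt$statistic), p_w = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$p_t))
    warning(sum(is.na(out$p_t)), " region(s) skipped: fewer than 2 animals")
  if (adjust == "BH") {
    out$p_t_adj <- stats::p.adjust(out$p_t, method = "BH")
    out$p_w_adj <- stats::p.adjust(out$p_w, method = "BH")
  }
  out
}

#' Full two-condition comparison
#'
#' Convenience driver running the whole contrast stage: per-condition
#' correlation matrices, thresholded networks, metric reports, the total
#' and locus-coeruleus connectivity contrasts, hemispheric edge counts,
#' positive-correlation fractions and per-region density tests.
#'
#' @param cohort_a,cohort_b `fos_cohort` objects for the two conditions.
#' @param alpha Edge significance threshold (default 0.05).
#' @param method P-value method passed to [correlation_matrix()].
#' @param lc_nodes Region codes for the node-level contrast
#'   (default `c("LC-L", "LC-R")`).
#' @return An object of class `fos_contrast` collecting all components.
#' @export
compare_conditions <- function(cohort_a, cohort_b, alpha = 0.05,
                               method = "auto",
                               lc_nodes = c("LC-L", "LC-R")) {
  corr_a <- correlation_matrix(cohort_a, method = method)
  corr_b <- correlation_matrix(cohort_b, method = method)
  net_a <- threshold_network(corr_a, alpha = alpha)
  net_b <- threshold_network(corr_b, alpha = alpha)
  z_a <- all_pairs_z(corr_a)
  z_b <- all_pairs_z(corr_b)
  lc <- lapply(stats::setNames(lc_nodes, lc_nodes), function(nd)
    node_connectivity_contrast(corr_a, corr_b, nd))
  structure(list(
    label_a = cohort_a$condition, label_b = cohort_b$condition,
    corr_a = corr_a, corr_b = corr_b,
    net_a = net_a, net_b = net_b,
    metrics_a = summarize_network(net_a),
    metrics_b = summarize_network(net_b),
    total_connectivity = total_connectivity_contrast(z_a, z_b),
    lc_contrast = lc,
    hemispheric_counts = list(a = hemispheric_counts(net_a),
                              b = hemispheric_counts(net_b)),
    positive_fraction = c(a = positive_fraction(corr_a),
                          b = positive_fraction(corr_b)),
    density_tests = regional_density_contrast(cohort_a, cohort_b)),
    class = "fos_contrast")
}

#' @export
print.fos_contrast <- function(x, ...) {
  tc <- x$total_connectivity
  cat("Condition contrast: ", x$label_a, " vs ", x$label_b, "\n", sep = "")
  cat(sprintf("  total connectivity (z): %.3f +/- %.3f vs %.3f +/- %.3f\n",
              tc$mean_a, tc$sem_a, tc$mean_b, tc$sem_b))
  cat(sprintf("  t(%d) = %.3f, p = %.3g; Kruskal-Wallis H = %.3f, p = %.3g\n",
              tc$df, tc$t, tc$p_t, tc$H, tc$p_kw))
  cat(sprintf("  significant edges: %d vs %d; positive fraction %.2f vs %.2f\n",
              nrow(x$net_a$edges), nrow(x$net_b$edges),
              x$positive_fraction["a"], x$positive_fraction["b"]))
  invisible(x)
}
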