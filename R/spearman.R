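# Exact permutation machinery for small-sample Spearman correlation.
#
# At the cohort sizes typical of c-Fos mapping (n = 8 animals per condition)
# the full permutation distribution of the Spearman coefficient is cheap to
# enumerate (8! = 40,320 rank assignments), so exact two-sided p-values are
# used by default for n <= 9 and the t approximation beyond that.

.fos_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an (n! x n) integer matrix.
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 10L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Null distribution of Spearman rho for untied samples of size n: the value
# of rho for every permutation of 1..n against the identity.  Cached.
spearman_null_rho <- function(n) {
  key <- paste0("null_rho_", n)
  if (!is.null(.fos_cache[[key]])) return(.fos_cache[[key]])
  P <- all_permutations(n)
  rho <- (12 * as.numeric(P %*% seq_len(n)) - 3 * n * (n + 1)^2) /
    (n * (n^2 - 1))
  .fos_cache[[key]] <- rho
  rho
}

# Sorted |rho| of the null distribution, for vectorized p-value lookup.
spearman_null_abs_sorted <- function(n) {
  key <- paste0("null_abs_", n)
  if (!is.null(.fos_cache[[key]])) return(.fos_cache[[key]])
  v <- sort(abs(spearman_null_rho(n)))
  .fos_cache[[key]] <- v
  v
}

# Two-sided exact p-values P(|rho_perm| >= |rho_obs|) for untied data,
# vectorized over observed rho.
exact_p_no_ties <- function(rho_obs, n) {
  v <- spearman_null_abs_sorted(n)
  m <- length(v)
  (m - findInterval(abs(rho_obs) - 1e-9, v)) / m
}

# Exact permutation p-value in the presence of ties: permute the observed
# (average) ranks of y against the ranks of x and count as-or-more-extreme
# |rho| values.
exact_p_with_ties <- function(rx, ry, rho_obs) {
  n <- length(rx)
  P <- all_permutations(n)
  xc <- rx - mean(rx)
  yperm <- matrix(ry[P], nrow(P), n)
  num <- as.numeric(yperm %*% xc)
  den <- sqrt(sum(xc^2) * sum((ry - mean(ry))^2))
  rho_perm <- num / den
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-9)
}

#' Spearman correlation for one region pair
#'
#' Computes the Spearman rank correlation between two density vectors across
#' animals, with pairwise-complete deletion of missing values, and a
#' two-sided p-value.  With `method = "exact"` the p-value is the fraction
#' of all n! rank assignments whose |rho| is at least the observed |rho|
#' (ties are handled by permuting the observed average ranks).  With
#' `method = "t_approx"` it uses the t statistic
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' `"auto"` (default) selects exact for n <= 9.
#'
#' @param x,y Numeric vectors of equal length (densities across animals).
#' @param method One of `"auto"`, `"exact"`, `"t_approx"`.
#' @return A list with elements `rho`, `p`, `n` (complete pairs used) and
#'   `method`.  A constant input yields `rho = NA`, `p = NA` with a warning
#'   (the correlation is undefined; no imputation is attempted).
#' @examples
#' spearman_pair(1:5, c(10, 20, 30, 40, 50))$rho   # 1
#' spearman_pair(1:5, 5:1)$rho                     # -1
#' @export
spearman_pair <- function(x, y, method = c("auto", "exact", "t_approx")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input: Spearman correlation undefined for this pair")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_exact <- switch(method, exact = TRUE, t_approx = FALSE, auto = n <= 9L)
  if (use_exact) {
    has_ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
    p <- if (has_ties) exact_p_with_ties(rx, ry, rho)
         else exact_p_no_ties(rho, n)
    used <- "exact"
  } else {
    p <- spearman_t_p(rho, n)
    used <- "t_approx"
  }
  list(rho = rho, p = p, n = n, method = used)
}

# Two-sided p from the t approximation; |rho| = 1 gives p = 0.
spearman_t_p <- function(rho, n) {
  p <- rep(0, length(rho))
  ok <- abs(rho) < 1
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[is.na(rho)] <- NA_real_
  p
}

#' Pairwise Spearman correlation matrix for a cohort
#'
#' Applies [spearman_pair()] to every unordered region pair of a cohort
#' (435 pairs for the default 30-region atlas), recording the coefficient,
#' two-sided p-value and effective sample size (pairwise-complete animals)
#' for each pair.  Pairs involving a constant region are left undefined
#' (`NA`) with one warning, never silently zeroed.
#'
#' @param cohort A `fos_cohort` with at least 3 animals.
#' @inheritParams spearman_pair
#' @return An object of class `fos_corr`: list with symmetric matrices
#'   `rho`, `pvals`, `n_pairs` (diagonal `NA`: self-correlation is not an
#'   edge), the `atlas`, the `condition` label and the p-value `method`.
#' @export
correlation_matrix <- function(cohort, method = c("auto", "exact", "t_approx")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "fos_cohort"))
  dens <- cohort$densities
  n_animal <- nrow(dens)
  if (n_animal < 3L) stop("need at least 3 animals for correlation inference")
  p_reg <- ncol(dens)
  codes <- colnames(dens)

  no_na <- !anyNA(dens)
  col_const <- apply(dens, 2L, function(v) length(unique(v[!is.na(v)])) <= 1L)
  col_tied <- apply(dens, 2L, function(v) anyDuplicated(v[!is.na(v)]) > 0L)
  use_exact <- switch(method, exact = TRUE, t_approx = FALSE,
                      auto = n_animal <= 9L)

  if (no_na && !any(col_const) && !(use_exact && any(col_tied))) {
    # fast path: single ranking per column, closed-form p lookup
    ranks <- apply(dens, 2L, rank)
    rho <- stats::cor(ranks)
    pvals <- matrix(NA_real_, p_reg, p_reg)
    ut <- upper.tri(rho)
    pvals[ut] <- if (use_exact) exact_p_no_ties(rho[ut], n_animal)
                 else spearman_t_p(rho[ut], n_animal)
    pvals[lower.tri(pvals)] <- t(pvals)[lower.tri(pvals)]
    n_pairs <- matrix(n_animal, p_reg, p_reg)
  } else {
    rho <- pvals <- matrix(NA_real_, p_reg, p_reg)
    n_pairs <- matrix(NA_integer_, p_reg, p_reg)
    n_undef <- 0L
    for (i in seq_len(p_reg - 1L)) {
      for (j in (i + 1L):p_reg) {
        res <- withCallingHandlers(
          tryCatch(spearman_pair(dens[, i], dens[, j], method = method),
                   error = function(e) list(rho = NA_real_, p = NA_real_,
                                            n = NA_integer_)),
          warning = function(w) invokeRestart("muffleWarning"))
        if (is.na(res$rho)) n_undef <- n_undef + 1L
        rho[i, j] <- rho[j, i] <- res$rho
        pvals[i, j] <- pvals[j, i] <- res$p
        n_pairs[i, j] <- n_pairs[j, i] <- res$n
      }
    }
    if (n_undef > 0L)
      warning(n_undef, " region pair(s) have undefined correlations ",
              "(constant input or too few complete pairs); left as NA")
  }
  diag(rho) <- NA_real_
  diag(pvals) <- NA_real_
  diag(n_pairs) <- NA_integer_
  dimnames(rho) <- dimnames(pvals) <- dimnames(n_pairs) <-
    list(codes, codes)
  structure(list(rho = rho, pvals = pvals, n_pairs = n_pairs,
                 atlas = cohort$atlas, condition = cohort$condition,
                 method = if (use_exact) "exact" else "t_approx"),
            class = "fos_corr")
}

#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(rho)`, the variance-stabilizing transform used as the
#' connectivity-strength scale.  Coefficients of exactly +/-1 are clamped to
#' +/-(1 - 1e-7) before the transform (with a warning) so the strength stays
#' finite.
#'
#' @param rho Numeric vector or matrix with `|rho| <= 1` (`NA` allowed).
#' @return `atanh(rho)` with the same shape.
#' @examples
#' fisher_z(0.5)   # 0.5493061
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE))
    stop("|rho| > 1 is not a correlation coefficient")
  clamp <- !is.na(rho) & abs(rho) == 1
  if (any(clamp)) {
    warning(sum(clamp), " coefficient(s) at +/-1 clamped to +/-(1 - 1e-7)")
    rho[clamp] <- sign(rho[clamp]) * (1 - 1e-7)
  }
  atanh(rho)
}

#' Connectivity strengths for all region pairs
#'
#' Fisher z-scores `atanh(rho)` for every unordered region pair, with no
#' significance filter and both signs retained — the "total connectivity"
#' vector whose between-condition comparison uses all C(30, 2) = 435 pairs
#' per condition.  Pair order is fixed by atlas order (row-major upper
#' triangle); undefined pairs are dropped with a warning.
#'
#' @param corr A `fos_corr`.
#' @return Named numeric vector, names `"<code_i>|<code_j>"`.
#' @export
all_pairs_z <- function(corr) {
  stopifnot(inherits(corr, "fos_corr"))
  codes <- rownames(corr$rho)
  p <- length(codes)
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p))
  rho <- corr$rho[cbind(i, j)]
  z <- fisher_z(rho)
  names(z) <- paste0(codes[i], "|", codes[j])
  if (anyNA(z)) {
    warning(sum(is.na(z)), " undefined pair(s) excluded from z vector")
    z <- z[!is.na(z)]
  }
  z
}

#' Threshold a correlation matrix into a functional network
#'
#' Keeps the region pairs whose two-sided p-value is strictly below `alpha`
#' (both positive and negative correlations) as the signed edge set, and
#' assigns Fisher-z connectivity strengths `atanh(rho)` to the significant
#' *positive* edges only; all other entries of the weight matrix are 0.
#'
#' @param corr A `fos_corr`.
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @param adjust P-value adjustment across the pair tests: `"none"`
#'   (default, uncorrected) or `"BH"` (Benjamini-Hochberg).
#' @return An object of class `fos_network`: list with `edges` (data frame
#'   `from`, `to`, `rho`, `p`, `n`, `sign`), `z_weights` (symmetric
#'   non-negative matrix, zero diagonal), `alpha`, `adjust`, `atlas`,
#'   `condition`.
#' @export
threshold_network <- function(corr, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(corr, "fos_corr"))
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  codes <- rownames(corr$rho)
  p <- length(codes)
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p))
  rho <- corr$rho[cbind(i, j)]
  pv <- corr$pvals[cbind(i, j)]
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  sig <- !is.na(pv) & pv < alpha
  edges <- data.frame(
    from = codes[i][sig], to = codes[j][sig],
    rho = rho[sig], p = pv[sig],
    n = corr$n_pairs[cbind(i, j)][sig],
    sign = ifelse(rho[sig] > 0, 1L, -1L),
    stringsAsFactors = FALSE)
  zw <- matrix(0, p, p, dimnames = list(codes, codes))
  pos <- sig & rho > 0
  if (any(pos)) {
    zv <- fisher_z(rho[pos])
    zw[cbind(i[pos], j[pos])] <- zv
    zw[cbind(j[pos], i[pos])] <- zv
  }
  structure(list(edges = edges, z_weights = zw, alpha = alpha,
                 adjust = adjust, atlas = corr$atlas,
                 condition = corr$condition),
            class = "fos_network")
}

#' @export
print.fos_corr <- function(x, ...) {
  p <- nrow(x$rho)
  cat("Spearman correlation matrix (", x$condition, "): ", p, " regions, ",
      p * (p - 1) / 2, " pairs, p-values: ", x$method, "\n", sep = "")
  invisible(x)
}

#' @export
print.fos_network <- function(x, ...) {
  cat("Functional network (", x$condition, "), p < ", x$alpha,
      if (x$adjust != "none") paste0(" [", x$adjust, "-adjusted]"), ": ",
      nrow(x$edges), " significant edges (",
      sum(x$edges$sign > 0), " positive, ", sum(x$edges$sign < 0),
      " negative)\n", sep = "")
  invisible(x)
}
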