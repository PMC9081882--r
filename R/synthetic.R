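# Gaussian-copula cohort generator with known ground-truth Spearman
# structure.  Target Spearman correlations are mapped to latent Pearson
# correlations through the exact bivariate-normal relation
# rho_P = 2 sin(pi rho_S / 6); the latent matrix is repaired to the nearest
# positive-semi-definite correlation matrix when needed (eigenvalue
# clipping), and each margin is pushed through a log-normal quantile
# function.  Ranks are untouched by the marginal transform, so the sample
# Spearman structure converges to the target regardless of the marginals.

#' Specification of a synthetic cohort
#'
#' @param n_animals Number of animals to simulate.
#' @param target_spearman Symmetric target Spearman matrix (unit diagonal,
#'   off-diagonal entries in (-1, 1)), dimnames = atlas codes.  Default:
#'   identity (independent regions).
#' @param marginal_params Data frame with columns `code`, `median`
#'   (cells/mm^2) and `cv` (coefficient of variation) for the log-normal
#'   margin of each region; default [default_marginals()].
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @param atlas A `fos_atlas`.
#' @param condition Condition label for the generated cohort.
#' @return An object of class `fos_synth_spec`.
#' @export
synthetic_spec <- function(n_animals = 8, target_spearman = NULL,
                           marginal_params = NULL, seed = 1L,
                           atlas = default_atlas(), condition = "synthetic") {
  p <- nrow(atlas)
  if (is.null(target_spearman)) {
    target_spearman <- diag(p)
    dimnames(target_spearman) <- list(atlas$code, atlas$code)
  }
  target_spearman <- as.matrix(target_spearman)
  if (!all(dim(target_spearman) == p))
    stop("target_spearman must be ", p, " x ", p)
  if (!isTRUE(all.equal(target_spearman, t(target_spearman),
                        tolerance = 1e-10)))
    stop("target_spearman must be symmetric")
  if (!isTRUE(all.equal(unname(diag(target_spearman)), rep(1, p))))
    stop("target_spearman must have unit diagonal")
  off <- target_spearman[upper.tri(target_spearman)]
  if (any(abs(off) >= 1))
    stop("off-diagonal target Spearman entries must lie in (-1, 1)")
  if (is.null(marginal_params)) marginal_params <- default_marginals(atlas)
  if (!all(c("code", "median", "cv") %in% names(marginal_params)))
    stop("marginal_params needs columns code, median, cv")
  if (!setequal(marginal_params$code, atlas$code))
    stop("marginal_params codes must match the atlas")
  if (any(marginal_params$median <= 0)) stop("marginal medians must be > 0")
  marginal_params <- marginal_params[match(atlas$code, marginal_params$code), ]
  structure(list(n_animals = as.integer(n_animals),
                 target_spearman = target_spearman,
                 marginal_params = marginal_params,
                 seed = as.integer(seed), atlas = atlas,
                 condition = condition),
            class = "fos_synth_spec")
}

#' Default log-normal marginal parameters
#'
#' Order-of-magnitude-plausible c-Fos density medians per anatomical group
#' (cells/mm^2) with a common coefficient of variation; purely cosmetic for
#' rank-based inference, configurable for realism.
#'
#' @param atlas A `fos_atlas`.
#' @param cv Coefficient of variation shared by all regions (default 0.4).
#' @return Data frame with `code`, `median`, `cv`.
#' @export
default_marginals <- function(atlas = default_atlas(), cv = 0.4) {
  med <- c(cortical = 150, hippocampal = 100, amygdalar = 80,
           thalamic = 120, brainstem = 60)
  data.frame(code = atlas$code,
             median = unname(med[atlas$display_group]),
             cv = cv, stringsAsFactors = FALSE)
}

# Map target Spearman to latent Pearson; exact under bivariate normality.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Nearest-PSD repair by eigenvalue clipping, rescaled to unit diagonal.
# Returns the repaired matrix with the Frobenius repair distance attached.
repair_psd <- function(S, eps = 1e-8) {
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) >= eps) {
    attr(S, "repair_distance") <- 0
    return(S)
  }
  vals <- pmax(eg$values, eps)
  R <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  d <- 1 / sqrt(diag(R))
  R <- R * tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- dimnames(S)
  attr(R, "repair_distance") <- sqrt(sum((R - S)^2))
  R
}

#' Generate a synthetic cohort from a specification
#'
#' Draws `n_animals` latent multivariate-normal vectors with the implied
#' Pearson correlation (PSD-repaired if necessary; the Frobenius repair
#' distance is reported via `message()` and stored as attribute
#' `repair_distance` on the result) and maps each margin through its
#' log-normal quantile function.  Identical specs give byte-identical
#' cohorts.
#'
#' @param spec A `fos_synth_spec`.
#' @return A `fos_cohort`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fos_synth_spec"))
  p <- nrow(spec$atlas)
  Sigma <- spearman_to_pearson(spec$target_spearman)
  diag(Sigma) <- 1
  Sigma <- repair_psd(Sigma)
  rd <- attr(Sigma, "repair_distance")
  if (rd > 0.1) {
    dev <- abs(Sigma - spearman_to_pearson(spec$target_spearman))
    diag(dev) <- 0
    worst <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("infeasible target correlation structure: ",
                        "PSD repair distance %.3f > 0.1 (worst pair %s - %s)"),
                 rd, rownames(Sigma)[worst[1]], colnames(Sigma)[worst[2]]))
  }
  if (rd > 0)
    message(sprintf("latent correlation repaired to PSD (Frobenius distance %.2e)",
                    rd))
  L <- chol(Sigma + diag(1e-10, p))
  Z <- withr::with_seed(
    spec$seed,
    matrix(stats::rnorm(spec$n_animals * p), spec$n_animals, p) %*% L)
  U <- stats::pnorm(Z)
  mp <- spec$marginal_params
  sdlog <- sqrt(log(1 + mp$cv^2))
  X <- vapply(seq_len(p), function(k)
    stats::qlnorm(U[, k], meanlog = log(mp$median[k]), sdlog = sdlog[k]),
    numeric(spec$n_animals))
  colnames(X) <- spec$atlas$code
  out <- cohort_table(X, condition = spec$condition, atlas = spec$atlas)
  attr(out, "repair_distance") <- rd
  out
}

#' Specification of a two-condition synthetic experiment
#'
#' Condition A uses the base target Spearman structure; condition B adds
#' three plantable effects, each capped so entries stay in
#' \[-`cap`, `cap`\] (default 0.85, keeping the joint target inside the
#' feasible set of rank-correlation matrices): a uniform increment to every
#' pair (`effect_global`), an extra increment to every inter-hemispheric
#' pair (`effect_interhemi`), and an extra increment to the locus coeruleus
#' couplings — LC-L with LC-R, and both LC with both dentate gyri
#' (`effect_lc`).
#'
#' @param base A `fos_synth_spec` for condition A.
#' @param effect_global Uniform Spearman increment in condition B.
#' @param effect_interhemi Additional increment for inter-hemispheric pairs.
#' @param effect_lc Additional increment for LC-LC and LC-DG pairs.
#' @param cap Absolute bound applied to condition B's off-diagonal targets.
#' @param label_a,label_b Condition labels.
#' @return An object of class `fos_pair_spec`.
#' @export
condition_pair_spec <- function(base, effect_global = 0,
                                effect_interhemi = 0, effect_lc = 0,
                                cap = 0.85,
                                label_a = "no_stim", label_b = "stim") {
  stopifnot(inherits(base, "fos_synth_spec"))
  atlas <- base$atlas
  T_a <- base$target_spearman
  T_b <- T_a
  off <- !diag(nrow(T_b))
  T_b[off] <- T_b[off] + effect_global
  hemi <- atlas$hemisphere
  cross <- outer(hemi, hemi, "!=")
  T_b[cross] <- T_b[cross] + effect_interhemi
  lc <- grep("^LC-", atlas$code)
  dg <- grep("^DG-", atlas$code)
  for (i in lc) for (j in c(lc, dg)) if (i != j)
    T_b[i, j] <- T_b[j, i] <- T_a[i, j] + effect_global +
      (if (cross[i, j]) effect_interhemi else 0) + effect_lc
  T_b[off] <- pmin(pmax(T_b[off], -cap), cap)
  spec_a <- synthetic_spec(base$n_animals, T_a, base$marginal_params,
                           seed = base$seed, atlas = atlas,
                           condition = label_a)
  spec_b <- synthetic_spec(base$n_animals, T_b, base$marginal_params,
                           seed = base$seed + 1L, atlas = atlas,
                           condition = label_b)
  structure(list(spec_a = spec_a, spec_b = spec_b,
                 effects = c(global = effect_global,
                             interhemi = effect_interhemi, lc = effect_lc)),
            class = "fos_pair_spec")
}

#' Generate a two-condition synthetic experiment
#'
#' @param pair_spec A `fos_pair_spec`.
#' @return List with `cohort_a`, `cohort_b` (sharing marginals, differing
#'   only in planted correlation structure) and `truth_a`, `truth_b`:
#'   logical matrices marking the planted (nonzero-target) region pairs.
#' @export
generate_condition_pair <- function(pair_spec) {
  stopifnot(inherits(pair_spec, "fos_pair_spec"))
  truth <- function(spec) {
    tm <- spec$target_spearman != 0
    diag(tm) <- FALSE
    tm
  }
  list(cohort_a = generate_cohort(pair_spec$spec_a),
       cohort_b = generate_cohort(pair_spec$spec_b),
       truth_a = truth(pair_spec$spec_a),
       truth_b = truth(pair_spec$spec_b))
}

#' Study-emulation preset
#'
#' Two conditions of `n_animals` each over the default 30-region atlas.
#' The base (condition A) structure encodes bilateral symmetry and
#' within-system coupling: homotopic left/right pairs 0.25, same-hemisphere
#' same-group pairs 0.30, same-hemisphere cross-group pairs 0.15,
#' inter-hemispheric same-group pairs 0.05, all other pairs 0.
#' Condition B adds `effect_global = 0.35`, `effect_interhemi = 0.15` and
#' `effect_lc = 0.40` (entries capped at 0.85), reproducing the qualitative
#' stimulation signature (higher total connectivity, inter-hemispheric
#' coupling, LC-LC and LC-DG coupling) at realistic strength; both
#' conditions' implied latent correlation matrices are positive definite
#' without repair.
#'
#' @param n_animals Animals per condition (default 8).
#' @param seed Integer seed.
#' @return A `fos_pair_spec`.
#' @export
study_preset <- function(n_animals = 8, seed = 1L) {
  atlas <- default_atlas()
  p <- nrow(atlas)
  name <- sub("-[LR]$", "", atlas$code)
  hemi <- atlas$hemisphere
  grp <- atlas$display_group
  T_a <- diag(p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    v <- 0
    same_h <- hemi[i] == hemi[j]
    same_g <- grp[i] == grp[j]
    if (name[i] == name[j]) v <- 0.25
    else if (same_h && same_g) v <- 0.30
    else if (same_h) v <- 0.15
    else if (same_g) v <- 0.05
    T_a[i, j] <- T_a[j, i] <- v
  }
  dimnames(T_a) <- list(atlas$code, atlas$code)
  base <- synthetic_spec(n_animals = n_animals, target_spearman = T_a,
                         seed = seed, atlas = atlas, condition = "no_stim")
  condition_pair_spec(base, effect_global = 0.35, effect_interhemi = 0.15,
                      effect_lc = 0.40, label_a = "no_stim", label_b = "stim")
}

#' Edge-recovery score of an inferred network against planted truth
#'
#' Confusion counts over all unordered region-pair slots (435 for the
#' default atlas): an edge of either sign in the inferred network is a
#' positive call.
#'
#' @param inferred A `fos_network`.
#' @param truth Logical matrix (codes x codes) marking true pairs, e.g.
#'   from [generate_condition_pair()].
#' @return List with `sensitivity`, `specificity`, `false_edges`,
#'   `true_edges`, and the raw counts `tp`, `fp`, `tn`, `fn`.
#' @export
recovery_score <- function(inferred, truth) {
  stopifnot(inherits(inferred, "fos_network"))
  codes <- inferred$atlas$code
  truth <- truth[codes, codes]
  inf_m <- matrix(FALSE, length(codes), length(codes),
                  dimnames = list(codes, codes))
  if (nrow(inferred$edges)) {
    idx <- cbind(match(inferred$edges$from, codes),
                 match(inferred$edges$to, codes))
    inf_m[idx] <- TRUE
    inf_m[idx[, 2:1, drop = FALSE]] <- TRUE
  }
  ut <- upper.tri(truth)
  tp <- sum(inf_m[ut] & truth[ut]); fp <- sum(inf_m[ut] & !truth[ut])
  fn <- sum(!inf_m[ut] & truth[ut]); tn <- sum(!inf_m[ut] & !truth[ut])
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       false_edges = fp, true_edges = tp,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
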