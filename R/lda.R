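# Two-class Fisher linear discriminant on a numeric matrix. Lean on purpose:
# it runs inside permutation loops (10^3-10^4 refits per test). Returns the
# unit normal of the separating hyperplane, the offset (hyperplane passes
# through the midpoint of the projected class means), projections, distances
# and the sign convention (group 1 projects above the hyperplane).
fisher_lda <- function(X, grp1, ridge = 0) {
  X1 <- X[grp1, , drop = FALSE]
  X2 <- X[!grp1, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  Sw <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X2, 2, mu2))) / (n1 + n2 - 2)
  if (ridge > 0) Sw <- Sw + diag(ridge, ncol(X))
  w <- tryCatch(solve(Sw, mu1 - mu2), error = function(e) NULL)
  if (is.null(w)) {
    w <- solve(Sw + diag(1e-6 * (sum(diag(Sw)) / ncol(X) + 1), ncol(X)), mu1 - mu2)
  }
  w <- w / sqrt(sum(w^2))
  proj <- drop(X %*% w)
  offset <- (sum(mu1 * w) + sum(mu2 * w)) / 2
  list(normal = w, offset = offset, projection = proj,
       distance = abs(proj - offset),
       mean_abs_distance = mean(abs(proj - offset)))
}

check_two_groups <- function(features, min_per_group = 2) {
  assert_cols(features, c("animal_id", "group"), "feature table")
  tab <- table(features$group)
  if (length(tab) != 2) {
    abort("Exactly two groups are required.", class = "ppiscale_domain_error")
  }
  if (any(tab < min_per_group)) {
    abort(sprintf("Each group needs >= %d animals.", min_per_group),
          class = "ppiscale_insufficient_data")
  }
  features$group == names(tab)[1]
}

#' Linear discriminant separation of two groups for one condition
#'
#' Standardizes the features across animals, fits a two-class linear
#' discriminant (pooled within-group covariance), and reports the mean
#' absolute distance of all animals from the separating hyperplane along
#' with each animal's projection onto the linear discriminant. A singular
#' within-group covariance falls back to a ridge-regularized solve with a
#' warning.
#'
#' @param features Feature table for a single condition with >= 3 animals
#'   per group (see [condition_features()], `"full"` type).
#' @param standardize z-score each feature across animals first (default).
#' @return Object of class `"ppi_lda"`: hyperplane `normal` and `offset`,
#'   per-animal `projections` tibble, and `mean_abs_distance`.
#' @export
lda_condition <- function(features, standardize = TRUE) {
  grp1 <- check_two_groups(features, min_per_group = 3)
  X <- feature_matrix(features, standardize)
  res <- fisher_lda(X, grp1)
  if (anyNA(res$normal)) {
    warn("Singular within-group covariance: ridge-regularized discriminant used.")
    res <- fisher_lda(X, grp1, ridge = 1e-6 * (sum(diag(stats::cov(X))) + 1))
  }
  structure(list(
    normal = setNames(res$normal, colnames(X)), offset = res$offset,
    projections = tibble(animal_id = features$animal_id,
                         group = features$group,
                         ld = res$projection,
                         distance = res$distance),
    mean_abs_distance = res$mean_abs_distance,
    groups = sort(unique(features$group))), class = "ppi_lda")
}

#' @export
print.ppi_lda <- function(x, ...) {
  cat(sprintf("<ppi_lda> %s vs %s: mean |distance| = %.3f\n",
              x$groups[1], x$groups[2], x$mean_abs_distance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ppi_lda <- function(x, ...) {
  tibble(term = names(x$normal), weight = unname(x$normal))
}

#' Permutation test on the LDA mean absolute distance
#'
#' Refits the discriminant under randomly permuted group labels and compares
#' the observed mean absolute distance from the hyperplane against the
#' permutation distribution, with the add-one estimator
#' `p = (1 + #(permuted >= observed)) / (n_perm + 1)`.
#'
#' @inheritParams lda_condition
#' @param n_perm Number of label permutations (default 10,000).
#' @param seed RNG seed.
#' @return One-row tibble: `mean_abs_distance`, `p_value`, `n_perm`.
#' @export
permutation_distance_test <- function(features, n_perm = 10000, seed = NULL,
                                      standardize = TRUE) {
  if (n_perm < 100) warn("Fewer than 100 permutations gives a coarse p-value.")
  grp1 <- check_two_groups(features, min_per_group = 3)
  X <- feature_matrix(features, standardize)
  obs <- fisher_stat(X, grp1)
  null_stats <- with_seed_if(seed, {
    vapply(seq_len(n_perm),
           function(i) fisher_stat(X, sample(grp1)),
           numeric(1))
  })
  tibble(mean_abs_distance = obs, p_value = perm_pvalue(null_stats, obs),
         n_perm = n_perm)
}

# Lean mean-absolute-distance statistic for permutation loops: identical to
# fisher_lda()'s mean_abs_distance but computed via class cross-products
# (no sweep/tryCatch overhead).
# Solve Sw w = d, ridging the scatter matrix when it is singular (fewer
# animals than features + 2, or collinear features).
solve_ridged <- function(Sw, d) {
  tryCatch(solve(Sw, d), error = function(e) {
    solve(Sw + diag(1e-8 * (sum(diag(Sw)) / ncol(Sw) + 1), ncol(Sw)), d)
  })
}

fisher_stat <- function(X, grp1) {
  X1 <- X[grp1, , drop = FALSE]; X2 <- X[!grp1, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  Sw <- (crossprod(X1) - n1 * tcrossprod(mu1) +
           crossprod(X2) - n2 * tcrossprod(mu2)) / (n1 + n2 - 2)
  w <- solve_ridged(Sw, mu1 - mu2)
  w <- w / sqrt(sum(w^2))
  offset <- sum((mu1 + mu2) / 2 * w)
  mean(abs(X %*% w - offset))
}

# Leave-one-out classification accuracy of the Fisher discriminant.
# Class means and cross-products are downdated per left-out animal
# (algebraically identical to refitting on the n-1 remaining animals).
loocv_accuracy <- function(X, grp1) {
  n <- nrow(X)
  X1 <- X[grp1, , drop = FALSE]; X2 <- X[!grp1, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  cp1 <- crossprod(X1); cp2 <- crossprod(X2)
  s1 <- colSums(X1); s2 <- colSums(X2)
  correct <- logical(n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    if (grp1[i]) {
      m1 <- (s1 - xi) / (n1 - 1); m2 <- s2 / n2
      Sw <- (cp1 - tcrossprod(xi) - (n1 - 1) * tcrossprod(m1) +
               cp2 - n2 * tcrossprod(m2)) / (n - 3)
    } else {
      m1 <- s1 / n1; m2 <- (s2 - xi) / (n2 - 1)
      Sw <- (cp1 - n1 * tcrossprod(m1) +
               cp2 - tcrossprod(xi) - (n2 - 1) * tcrossprod(m2)) / (n - 3)
    }
    w <- solve_ridged(Sw, m1 - m2)
    side <- sum(xi * w) > sum((m1 + m2) / 2 * w)
    correct[i] <- side == grp1[i]
  }
  mean(correct)
}

#' Leave-one-out LDA classification accuracy with permutation test
#'
#' Classifies each animal with a discriminant trained on all other animals
#' and reports the accuracy, together with a permutation p-value from
#' label-shuffled accuracies.
#'
#' @inheritParams permutation_distance_test
#' @return One-row tibble: `accuracy`, `p_value`, `n_perm`.
#' @export
loocv_accuracy_test <- function(features, n_perm = 10000, seed = NULL,
                                standardize = TRUE) {
  grp1 <- check_two_groups(features, min_per_group = 2)
  if (length(grp1) < 4) {
    abort("Need >= 4 animals for leave-one-out cross-validation.",
          class = "ppiscale_insufficient_data")
  }
  X <- feature_matrix(features, standardize)
  obs <- loocv_accuracy(X, grp1)
  null_stats <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) loocv_accuracy(X, sample(grp1)),
           numeric(1))
  })
  tibble(accuracy = obs, p_value = perm_pvalue(null_stats, obs), n_perm = n_perm)
}

#' Run the LDA separability battery per condition
#'
#' Applies [lda_condition()], [permutation_distance_test()] and
#' [loocv_accuracy_test()] to every prepulse condition in a feature table.
#' Conditions carrying different `condition_tag` values (prepulse-varying
#' versus delay-varying experiments) are analysed separately and never
#' pooled.
#'
#' @param features Full (5-feature) table for two groups across conditions.
#' @param n_perm Permutations per test.
#' @param seed RNG seed (split deterministically across conditions).
#' @return Tibble with one row per condition: mean absolute distance and its
#'   permutation p, LOOCV accuracy and its permutation p.
#' @export
lda_by_condition <- function(features, n_perm = 10000, seed = NULL) {
  pieces <- features %>%
    group_by(across(all_of(intersect(c("condition_tag", "prepulse_db", "delay_ms"),
                                     names(features))))) %>%
    dplyr::group_split()
  seeds <- child_seeds(seed, length(pieces))
  purrr::map2(pieces, seeds, function(d, s) {
    ss <- child_seeds(s, 2)
    dist <- permutation_distance_test(d, n_perm, seed = ss[[1]])
    acc <- loocv_accuracy_test(d, n_perm, seed = ss[[2]])
    tibble(prepulse_db = d$prepulse_db[[1]], delay_ms = d$delay_ms[[1]],
           condition_tag = if ("condition_tag" %in% names(d)) d$condition_tag[[1]] else NA_character_,
           mean_abs_distance = dist$mean_abs_distance,
           distance_p = dist$p_value,
           loocv_accuracy = acc$accuracy, loocv_p = acc$p_value,
           n_perm = n_perm)
  }) %>% bind_rows()
}

#' Bootstrapped ratio test for the number of significant conditions
#'
#' Multiplicity control for per-condition tests: under the null, each of the
#' `n_conditions` tests is independently significant with probability
#' `alpha`; the test asks whether observing `k_significant` significant
#' conditions is surprising, by drawing `n_boot` binomial counts and using
#' the add-one tail estimator. (This independence null ignores dependence
#' between conditions measured on the same animals.)
#'
#' @param k_significant Observed number of significant conditions.
#' @param n_conditions Number of conditions tested.
#' @param alpha Per-condition significance level.
#' @param n_boot Number of bootstrap draws.
#' @param seed RNG seed.
#' @return One-row tibble: `k_significant`, `n_conditions`, `p_value`,
#'   and the exact binomial tail `p_exact` for reference.
#' @export
ratio_multiplicity_test <- function(k_significant, n_conditions, alpha = 0.05,
                                    n_boot = 10000, seed = NULL) {
  stopifnot(k_significant >= 0, k_significant <= n_conditions)
  counts <- with_seed_if(seed, rbinom(n_boot, n_conditions, alpha))
  tibble(k_significant = k_significant, n_conditions = n_conditions,
         p_value = perm_pvalue(counts, k_significant),
         p_exact = stats::pbinom(k_significant - 1, n_conditions, alpha,
                                 lower.tail = FALSE))
}
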