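# Independent reference implementations used to cross-check the package.
# Deliberately written as plain loops over the definitions, sharing no
# code with the implementation under test.

# Threshold expansion/contraction indices by direct enumeration.
oracle_indices <- function(repeats, weights, threshold = 0.05) {
  modal_w <- max(weights)
  modal_r <- min(repeats[weights == modal_w])
  keep_r <- c(); keep_w <- c()
  for (i in seq_along(repeats)) {
    if (weights[i] >= threshold * modal_w) {
      keep_r <- c(keep_r, repeats[i])
      keep_w <- c(keep_w, weights[i])
    }
  }
  total <- sum(keep_w)
  e_idx <- 0; c_idx <- 0
  for (i in seq_along(keep_r)) {
    d <- keep_r[i] - modal_r
    if (d > 0) e_idx <- e_idx + (keep_w[i] / total) * d
    if (d < 0) c_idx <- c_idx + (keep_w[i] / total) * (-d)
  }
  list(expansion = e_idx, contraction = c_idx, retained = length(keep_r))
}

# Pearson chi-square from first principles.
oracle_chisq <- function(m) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  list(statistic = stat, df = (nrow(m) - 1) * (ncol(m) - 1))
}

# Wrap a raw count triple as the classification result type.
make_class_counts <- function(contracted, modal, expanded) {
  structure(
    list(n_contracted = contracted, n_modal = modal, n_expanded = expanded,
         n_total = contracted + modal + expanded,
         modal_reference = NA_integer_, bins = NULL),
    class = "class_counts"
  )
}

# Small cortical/subcortical panel for planted-partition checks.
two_block_panel <- function() {
  list(
    tissue_profile("ctx_a", 0.022, 0.18, block = "cortical"),
    tissue_profile("ctx_b", 0.023, 0.18, block = "cortical"),
    tissue_profile("ctx_c", 0.024, 0.18, block = "cortical"),
    tissue_profile("sub_a", 0.013, 0.18, block = "subcortical"),
    tissue_profile("sub_b", 0.014, 0.18, block = "subcortical"),
    tissue_profile("sub_c", 0.015, 0.18, block = "subcortical")
  )
}

# Did column clustering split the panel exactly into its two blocks?
blocks_recovered <- function(col_clusters) {
  blocks <- substr(names(col_clusters), 1, 3)
  per_block <- tapply(col_clusters, blocks, function(x) length(unique(x)))
  all(per_block == 1) && length(unique(col_clusters)) == 2
}

# Cheap single-tissue profile for cohort-level statistics where the
# somatic distributions themselves are irrelevant.
minimal_profile <- function() list(tissue_profile("blood", 0.004, 0.05))
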