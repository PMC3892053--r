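# Metabolizer-subpopulation detection and comparison, and breed half-life
# statistics.

# exact 1-D two-means on a sorted vector: try every split point, minimize
# total within-cluster sum of squares
.two_means_1d <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best_ss <- Inf
  best_k <- 1L
  for (k in seq_len(n - 1)) {
    lo <- xs[1:k]; hi <- xs[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) { best_ss <- ss; best_k <- k }
  }
  lo <- xs[1:best_k]; hi <- xs[(best_k + 1):n]
  list(centers = c(mean(lo), mean(hi)), split_value = (max(lo) + min(hi)) / 2,
       within_ss = best_ss, sizes = c(best_k, n - best_k))
}

#' Classify subjects into extensive/poor metabolizers from half-lives
#'
#' Splits log terminal half-lives into two clusters by exact one-dimensional
#' two-means; subjects above the midpoint of the cluster centers are labeled
#' poor metabolizers (PM, slow elimination), the rest extensive metabolizers
#' (EM). A bimodality flag reports whether the cluster separation is at
#' least twice the pooled within-cluster standard deviation; when the data
#' are unimodal the split is still returned but flagged.
#'
#' @param halflives Named numeric vector of per-subject terminal half-lives
#'   (h); names are subject ids (defaults to indices).
#' @return List of class `metabolizer_assignment`: data.frame `assignments`
#'   (subject_id, label, basis_halflife), `bimodal` flag, cluster `centers`
#'   (h, back-transformed), `separation_ratio`.
#' @export
classify_metabolizers <- function(halflives) {
  stopifnot(is.numeric(halflives), all(halflives > 0))
  n <- length(halflives)
  if (n < 4) stop("classify_metabolizers: need >= 4 subjects")
  ids <- names(halflives)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  lx <- log(halflives)

  if (max(lx) - min(lx) < .Machine$double.eps^0.5) {
    return(structure(list(
      assignments = data.frame(subject_id = ids, label = "EM",
                               basis_halflife = halflives,
                               stringsAsFactors = FALSE),
      bimodal = FALSE, centers = rep(exp(mean(lx)), 2),
      separation_ratio = 0), class = "metabolizer_assignment"))
  }
  km <- .two_means_1d(lx)
  mid <- mean(km$centers)
  label <- ifelse(lx > mid, "PM", "EM")
  pooled_df <- max(sum(km$sizes) - 2, 1)
  pooled_sd <- sqrt(km$within_ss / pooled_df)
  sep <- diff(km$centers)
  ratio <- if (pooled_sd > 0) sep / pooled_sd else Inf
  structure(list(
    assignments = data.frame(subject_id = ids, label = label,
                             basis_halflife = halflives,
                             stringsAsFactors = FALSE),
    bimodal = ratio >= 2, centers = exp(km$centers),
    separation_ratio = ratio), class = "metabolizer_assignment")
}

#' Compare a PK parameter between two subject subgroups
#'
#' Welch (unequal-variance) unpaired t-test between the two groups, plus
#' the fold ratio of the group means (larger over smaller).
#'
#' @param values_by_label Named list of two numeric vectors (e.g.
#'   `list(EM = ..., PM = ...)`), each of length >= 2.
#' @param parameter_name Label for reporting.
#' @param alpha Significance level for the marker (default 0.05).
#' @return List of class `subgroup_comparison`: `group_means`, `group_sds`,
#'   `p_value`, `fold_ratio`, `significant`, `parameter`.
#' @export
compare_subgroups <- function(values_by_label, parameter_name = "parameter",
                              alpha = 0.05) {
  stopifnot(is.list(values_by_label), length(values_by_label) == 2)
  g1 <- values_by_label[[1]]; g2 <- values_by_label[[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("compare_subgroups: both groups need n >= 2")
  m <- c(mean(g1), mean(g2)); s <- c(sd(g1), sd(g2))
  names(m) <- names(s) <- names(values_by_label)
  if (s[1] == 0 && s[2] == 0) {
    p <- if (m[1] == m[2]) 1 else 0
  } else {
    p <- t.test(g1, g2, var.equal = FALSE)$p.value
  }
  if (any(m <= 0)) stop("compare_subgroups: fold ratio needs positive means")
  structure(list(group_means = m, group_sds = s, p_value = p,
                 fold_ratio = max(m) / min(m), significant = p < alpha,
                 parameter = parameter_name),
            class = "subgroup_comparison")
}

# compact letter display from a logical "significantly different" matrix,
# via maximal cliques of the non-significance graph (groups in mean order)
.letter_groups <- function(sig_mat, means) {
  k <- nrow(sig_mat)
  nonsig <- !sig_mat
  diag(nonsig) <- FALSE # neighbor sets must not contain the vertex itself
  # Bron-Kerbosch without pivoting; k is small (breed tables)
  cliques <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      cliques[[length(cliques) + 1L]] <<- r
      return(invisible())
    }
    for (v in p) {
      nv <- which(nonsig[v, ])
      bk(c(r, v), intersect(p, nv), intersect(x, nv))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  # order cliques by the smallest group mean they contain
  cliques <- cliques[order(vapply(cliques, function(cl) min(means[cl]), numeric(1)))]
  letters_out <- rep("", k)
  for (i in seq_along(cliques)) {
    for (g in cliques[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  }
  letters_out
}

#' Breed half-life descriptive statistics and one-way ANOVA
#'
#' Per-breed descriptive summaries (n, min, max, mean, SD, CV%), a one-way
#' fixed-effect ANOVA of half-life on breed, and Tukey HSD post-hoc
#' pairwise comparisons rendered as compact letter groups (breeds sharing a
#' letter are not significantly different at `alpha`).
#'
#' @param halflives_by_breed Named list of numeric vectors, one per breed
#'   (>= 2 breeds, each n >= 2).
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @return List of class `breed_anova`: data.frame `summaries` (breed, n,
#'   min, max, mean, sd, cv, letter_group), `p_value`, `tukey` (the
#'   TukeyHSD table).
#' @export
breed_anova <- function(halflives_by_breed, alpha = 0.05) {
  stopifnot(is.list(halflives_by_breed), length(halflives_by_breed) >= 2)
  ns <- lengths(halflives_by_breed)
  if (any(ns < 2)) stop("breed_anova: every breed needs n >= 2")
  breeds <- names(halflives_by_breed)
  if (is.null(breeds)) breeds <- paste0("breed", seq_along(halflives_by_breed))
  df <- data.frame(
    halflife = unlist(halflives_by_breed, use.names = FALSE),
    breed = factor(rep(breeds, ns), levels = breeds))
  fit <- aov(halflife ~ breed, data = df)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$breed

  k <- length(breeds)
  sig <- matrix(FALSE, k, k, dimnames = list(breeds, breeds))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    s <- tk[rn, "p adj"] < alpha
    sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- s
  }
  mu <- vapply(halflives_by_breed, mean, numeric(1))
  sdv <- vapply(halflives_by_breed, sd, numeric(1))
  summaries <- data.frame(
    breed = breeds, n = as.integer(ns),
    min = vapply(halflives_by_breed, min, numeric(1)),
    max = vapply(halflives_by_breed, max, numeric(1)),
    mean = mu, sd = sdv,
    cv = ifelse(mu > 0, sdv / mu * 100, NA_real_),
    letter_group = .letter_groups(sig, mu),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(summaries = summaries, p_value = p, tukey = tk),
            class = "breed_anova")
}
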