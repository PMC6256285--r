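# Cohort construction and the statistical test battery: equal events per
# cell, Kolmogorov-Smirnov on cumulative distributions (alpha = 0.005),
# Kruskal-Wallis with Dunn's correction for more than two groups, and the
# Wilcoxon / Mann-Whitney / two-way-ANOVA-with-Sidak layer (alpha = 0.05).

#' Build a cohort of equal events per cell
#'
#' Pools a random selection of exactly `n_per_cell` values from every cell,
#' giving each cell equal representation in cumulative distributions (e.g.
#' 600 events from 12 cells at 50 per cell).
#'
#' @param per_cell_values Named list mapping cell id to its values; every
#'   cell must hold at least `n_per_cell` values.
#' @param n_per_cell Values sampled per cell (without replacement by
#'   default).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @param replace Sample with replacement (default FALSE).
#' @return A `cohort`: data frame of `value` and `cell` plus the sampling
#'   parameters.
#' @export
sample_cohort <- function(per_cell_values, n_per_cell, seed = NULL,
                          replace = FALSE) {
  if (is.null(names(per_cell_values)))
    names(per_cell_values) <- paste0("cell", seq_along(per_cell_values))
  short <- names(per_cell_values)[
    vapply(per_cell_values, length, integer(1)) < n_per_cell & !replace]
  if (length(short) > 0)
    stop(sprintf("cell(s) %s hold fewer than %d values",
                 paste(short, collapse = ", "), n_per_cell), call. = FALSE)
  with_seed(seed, {
    picks <- lapply(per_cell_values, function(v)
      v[sample.int(length(v), n_per_cell, replace = replace)])
    structure(list(
      data = data.frame(
        value = unlist(picks, use.names = FALSE),
        cell = rep(names(per_cell_values), each = n_per_cell)),
      n_per_cell = as.integer(n_per_cell), seed = seed,
      replace = replace), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d values = %d cells x %d per cell\n",
              nrow(x$data), length(unique(x$data$cell)), x$n_per_cell))
  invisible(x)
}

cohort_values <- function(x) {
  if (inherits(x, "cohort")) x$data$value else as.numeric(x)
}

#' Compare cumulative distributions between cohorts
#'
#' Two cohorts are compared with the two-sample Kolmogorov-Smirnov test at
#' the stringent alpha = 0.005 convention for cumulative distributions.
#' Three or more cohorts are compared with Kruskal-Wallis followed by
#' Dunn's corrected post hoc pairwise comparisons.
#'
#' @param ... Two or more cohorts (or numeric vectors).
#' @param alpha Significance level (default 0.005 for the two-sample KS
#'   path; Dunn's post hocs use 0.05 unless overridden).
#' @return For two groups: list with `method`, `statistic` (KS D), `p_value`
#'   and `significant`. For more: the Kruskal-Wallis omnibus plus a data
#'   frame of Dunn's z tests.
#' @export
compare_distributions <- function(..., alpha = 0.005) {
  groups <- lapply(list(...), cohort_values)
  if (length(groups) == 1 && is.list(groups[[1]]))
    groups <- lapply(groups[[1]], cohort_values)
  if (length(groups) < 2) stop("need at least two cohorts", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("cohorts must be non-empty", call. = FALSE)
  if (length(groups) == 2) {
    if (identical(groups[[1]], groups[[2]])) {
      # identical samples: D = 0 and no evidence against the null
      return(list(method = "two-sample Kolmogorov-Smirnov", statistic = 0,
                  p_value = 1, significant = FALSE, alpha = alpha))
    }
    ks <- suppressWarnings(ks.test(groups[[1]], groups[[2]]))
    return(list(method = "two-sample Kolmogorov-Smirnov",
                statistic = unname(ks$statistic),
                p_value = ks$p.value,
                significant = ks$p.value < alpha, alpha = alpha))
  }
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kw <- kruskal.test(values, g)
  dunn <- dunn_posthoc(values, g)
  list(method = "Kruskal-Wallis with Dunn's correction",
       statistic = unname(kw$statistic), p_value = kw$p.value,
       significant = kw$p.value < 0.05, posthoc = dunn, alpha = alpha)
}

# Dunn's z tests on the pooled Kruskal-Wallis ranks, two-sided, with the
# Bonferroni-style multiplication over comparisons ("Dunn's correction").
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  # tie correction term
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  mean_rank <- tapply(r, groups, mean)
  n_i <- tapply(r, groups, length)
  combs <- utils::combn(seq_along(lev), 2)
  m <- ncol(combs)
  out <- data.frame(group1 = lev[combs[1, ]], group2 = lev[combs[2, ]],
                    z = NA_real_, p_adjusted = NA_real_)
  for (k in seq_len(m)) {
    i <- combs[1, k]; j <- combs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_i[i] + 1 / n_i[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    out$z[k] <- z
    out$p_adjusted[k] <- min(1, 2 * pnorm(-abs(z)) * m)
  }
  out
}

#' Paired, unpaired and factorial test dispatch
#'
#' The per-cell comparison layer: Wilcoxon matched-pairs signed-rank for
#' paired designs, Mann-Whitney for unpaired, and two-way ANOVA with
#' Sidak-corrected within-genotype post hoc comparisons for factorial
#' (genotype x treatment) designs. Significance at alpha = 0.05.
#'
#' @param before,after Paired (aligned by cell; names checked when present)
#'   or unpaired value vectors. Ignored for the factorial design.
#' @param design `"paired"`, `"unpaired"` or `"factorial"`.
#' @param data For `design = "factorial"`: data frame with columns `value`,
#'   `genotype`, `treatment` (and optionally `cell`).
#' @param alpha Significance level (default 0.05).
#' @return A list with `method`, `p_value` (or the ANOVA table plus post
#'   hoc contrasts) and `significant`.
#' @export
paired_tests <- function(before = NULL, after = NULL,
                         design = c("paired", "unpaired", "factorial"),
                         data = NULL, alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(before) != length(after))
      stop("paired inputs must be aligned cell-by-cell", call. = FALSE)
    if (!is.null(names(before)) && !is.null(names(after)) &&
        !identical(names(before), names(after)))
      stop("paired inputs must be aligned cell-by-cell (names differ)",
           call. = FALSE)
    ht <- suppressWarnings(wilcox.test(before, after, paired = TRUE,
                                       exact = FALSE))
    p <- if (is.nan(ht$p.value)) 1 else ht$p.value
    return(list(method = "Wilcoxon matched-pairs signed rank",
                p_value = p, significant = p < alpha, alpha = alpha))
  }
  if (design == "unpaired") {
    ht <- suppressWarnings(wilcox.test(before, after, exact = FALSE))
    return(list(method = "Mann-Whitney", p_value = ht$p.value,
                significant = ht$p.value < alpha, alpha = alpha))
  }
  # factorial genotype x treatment with Sidak-corrected within-genotype
  # treatment comparisons
  if (is.null(data) || !all(c("value", "genotype", "treatment") %in%
                              names(data)))
    stop("factorial design needs `data` with value, genotype, treatment",
         call. = FALSE)
  data$genotype <- factor(data$genotype)
  data$treatment <- factor(data$treatment)
  fit <- aov(value ~ genotype * treatment, data = data)
  em <- emmeans::emmeans(fit, ~ treatment | genotype)
  contrasts <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                               adjust = "sidak"))
  list(method = "two-way ANOVA with Sidak post hoc",
       anova = summary(fit), posthoc = contrasts,
       significant = any(contrasts$p.value < alpha), alpha = alpha)
}
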