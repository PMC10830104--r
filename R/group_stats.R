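# Category-level comparison of normalized uptake: one-way ANOVA across ion
# categories and a Tukey-Kramer post hoc (chosen for its handling of unequal
# group sizes), summarized with a compact letter display.

#' Ion category assignment for a salt panel
#'
#' Maps each salt to the biological category of its cation and anion, the
#' grouping used for category-level uptake comparisons: macronutrient
#' cations (K+, NH4+), secondary nutrients (Ca2+, Mg2+), sodium, and heavy
#' metals (Ag+, Ba2+, Cd2+, Cu2+, La3+, Ni2+, Gd3+).
#'
#' @param salt_names Character vector of salt formulas known to the bundled
#'   ion table (see [ion_reference_table()]).
#' @return Data.frame with `salt_name`, `cation_category`, `anion_category`.
#' @export
assign_ion_categories <- function(salt_names) {
  feats <- build_feature_table(salt_names)
  data.frame(salt_name = feats$salt_name,
             cation_category = feats$cation_nutrient_class,
             anion_category = feats$anion_nutrient_class,
             stringsAsFactors = FALSE)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F is the ratio of between-group to
#' within-group mean squares with (g - 1, n - g) degrees of freedom, computed
#' through a standard linear-model fit. When both the between- and
#' within-group sums of squares are zero the statistic is undefined and
#' flagged rather than returned as NaN.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   non-empty, total n > number of groups).
#' @return List with `F`, `df_between`, `df_within`, `p`, `undefined`.
#' @examples
#' one_way_anova(list(rnorm(5), rnorm(7, 1), rnorm(6, 2)))
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one value", call. = FALSE)
  n <- sum(sizes)
  g <- length(groups)
  if (n <= g) stop("total sample size must exceed the number of groups",
                   call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_len(g), sizes))
  # an essentially-perfect fit (zero residual SS) warns inside anova(); that
  # degenerate case is detected and flagged explicitly below
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ fac)))
  ssb <- tab$`Sum Sq`[1L]
  ssw <- tab$`Sum Sq`[2L]
  tol <- 1e-12 * (sum(y^2) + 1)    # float-noise floor for exact-zero SS
  if (ssw <= tol && ssb <= tol) {
    return(list(F = NA_real_, df_between = g - 1L, df_within = n - g,
                p = NA_real_, undefined = TRUE))
  }
  Fval <- unname(tab$`F value`[1L])
  list(F = Fval, df_between = g - 1L, df_within = n - g,
       p = unname(tab$`Pr(>F)`[1L]), undefined = FALSE)
}

#' Tukey-Kramer post hoc comparison with compact letters
#'
#' All pairwise comparisons of group means after a one-way ANOVA, using the
#' studentized-range statistic with Kramer's unequal-sample-size standard
#' error `sqrt(MSE/2 * (1/n_i + 1/n_j))`; for equal n this reduces to the
#' classical Tukey HSD. Critical values come from the studentized-range
#' distribution (`qtukey`/`ptukey`), so any number of groups is supported.
#' Groups are additionally summarized by a compact letter display
#' (insert-and-absorb): groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param groups List of numeric vectors, one per group; each of size >= 2.
#' @param alpha Family-wise significance level (default 0.05).
#' @param group_names Optional names; default `g1`, `g2`, ...
#' @return List of class `tukey_kramer` with `pairs` (data.frame: `i`, `j`,
#'   `mean_diff`, `se`, `q`, `p_adj`, `significant`), `letters` (named
#'   character), `means`, `n`, `mse`, `df_error`, `alpha`, `q_crit`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05, group_names = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values for the pooled variance",
         call. = FALSE)
  }
  g <- length(groups)
  if (is.null(group_names)) group_names <- paste0("g", seq_len(g))
  stopifnot(length(group_names) == g)
  means <- vapply(groups, mean, numeric(1L))
  n <- sum(sizes)
  df_err <- n - g
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L))) /
    df_err
  q_crit <- stats::qtukey(1 - alpha, nmeans = g, df = df_err)
  combs <- utils::combn(g, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(kk) {
    i <- combs[1L, kk]; j <- combs[2L, kk]
    se <- sqrt(mse / 2 * (1 / sizes[i] + 1 / sizes[j]))
    diffm <- means[i] - means[j]
    q <- if (se == 0) {
      if (diffm == 0) 0 else Inf
    } else abs(diffm) / se
    p_adj <- stats::ptukey(q, nmeans = g, df = df_err, lower.tail = FALSE)
    data.frame(i = group_names[i], j = group_names[j], mean_diff = diffm,
               se = se, q = q, p_adj = p_adj, significant = p_adj < alpha,
               stringsAsFactors = FALSE)
  }))
  letters_out <- compact_letter_display(group_names, means, pairs)
  structure(list(pairs = pairs, letters = letters_out,
                 means = stats::setNames(means, group_names),
                 n = stats::setNames(as.integer(sizes), group_names),
                 mse = mse, df_error = df_err, alpha = alpha, q_crit = q_crit),
            class = "tukey_kramer")
}

# Insert-and-absorb compact letter display. Groups are ordered by descending
# mean; letters are sets of mutually non-significant groups.
compact_letter_display <- function(group_names, means, pairs) {
  ord <- order(-means)
  names_ord <- group_names[ord]
  sig <- pairs[pairs$significant, c("i", "j"), drop = FALSE]
  sets <- list(names_ord)   # start: everyone shares one letter
  for (r in seq_len(nrow(sig))) {
    a <- sig$i[r]; b <- sig$j[r]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[u] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v)) {
          keep[u] <- FALSE
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  # order letters by the best (highest-mean) group they contain
  first_rank <- vapply(sets, function(s) min(match(s, names_ord)), numeric(1L))
  sets <- sets[order(first_rank)]
  out <- stats::setNames(rep("", length(group_names)), group_names)
  for (li in seq_along(sets)) {
    lab <- letters[li]
    for (gn in sets[[li]]) out[gn] <- paste0(out[gn], lab)
  }
  # stable within-group letter order
  out[] <- vapply(out, function(s) {
    paste(sort(strsplit(s, "")[[1L]]), collapse = "")
  }, character(1L))
  out
}

#' @export
print.tukey_kramer <- function(x, ...) {
  cat(sprintf("<tukey_kramer> %d groups, MSE = %.4g, df = %d, q_crit(%.2f) = %.3f\n",
              length(x$means), x$mse, x$df_error, x$alpha, x$q_crit))
  df <- data.frame(group = names(x$means), mean = unname(x$means),
                   n = unname(x$n), letter = unname(x$letters[names(x$means)]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Category-level uptake summary
#'
#' Groups a batch uptake results table by ion category (cation or anion),
#' runs the one-way ANOVA and Tukey-Kramer post hoc, and emits a per-category
#' summary of mean normalized uptake with a 95% confidence interval, sample
#' size and compact letter.
#'
#' @param results Data.frame from [run_uptake_batch()] (plant rows with
#'   finite `ratio` are used).
#' @param categories Data.frame from [assign_ion_categories()].
#' @param ion Which ion's category to group by: `"cation"` or `"anion"`.
#' @param alpha Significance level.
#' @return List with `anova`, `posthoc`, and `summary` (data.frame:
#'   `category`, `mean`, `ci_lo`, `ci_hi`, `n`, `letter`).
#' @export
category_uptake_summary <- function(results, categories, ion = c("cation", "anion"),
                                    alpha = 0.05) {
  ion <- match.arg(ion)
  col <- paste0(ion, "_category")
  df <- merge(results[results$role == "plant" & is.finite(results$ratio), ],
              categories, by = "salt_name")
  if (nrow(df) == 0L) stop("no plant results with finite ratios", call. = FALSE)
  split_vals <- split(df$ratio, df[[col]])
  split_vals <- split_vals[lengths(split_vals) > 0L]
  aov_res <- one_way_anova(split_vals)
  th <- tukey_kramer(split_vals, alpha = alpha, group_names = names(split_vals))
  summ <- do.call(rbind, lapply(names(split_vals), function(gn) {
    v <- split_vals[[gn]]
    m <- mean(v)
    half <- if (length(v) > 1L) {
      stats::qt(1 - alpha / 2, df = length(v) - 1L) * stats::sd(v) / sqrt(length(v))
    } else NA_real_
    data.frame(category = gn, mean = m, ci_lo = m - half, ci_hi = m + half,
               n = length(v), letter = unname(th$letters[gn]),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(-summ$mean), ]
  rownames(summ) <- NULL
  list(anova = aov_res, posthoc = th, summary = summ)
}
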