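## Downstream genetics statistics: Pearson correlations with significance
## stars, genotype ANOVA with Tukey-Kramer compact letters, and broad-sense
## heritability from ANOVA mean squares.

#' Pearson correlation with significance stars
#'
#' Sample Pearson r with a two-sided p-value from the t statistic
#' `r * sqrt((n - 2)/(1 - r^2))` on n - 2 df (via [stats::cor.test()]), or an
#' exact permutation p-value for small samples. Stars follow the usual
#' convention at alpha = 0.05: `NS` (p >= 0.05), `*` (p < 0.05), `**`
#' (p < 0.01), `***` (p < 0.001).
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped;
#'   n >= 3 complete pairs and non-zero variance required.
#' @param method `"t"` (default) or `"permutation"` (exact for n < 10,
#'   otherwise 10000 random permutations).
#' @return A one-row tibble: `r`, `p_value`, `stars`, `n`.
#' @export
pearson_with_stars <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) ct_abort("need at least 3 complete pairs", "ct_error_too_few")
  if (var(x) == 0 || var(y) == 0) {
    ct_abort("zero variance", "ct_error_zero_variance")
  }
  r <- stats::cor(x, y)
  p <- if (method == "t") {
    stats::cor.test(x, y)$p.value
  } else {
    perms <- if (n < 10L) {
      apply(permutations_of(n), 1L, function(pm) stats::cor(x, y[pm]))
    } else {
      replicate(10000L, stats::cor(x, sample(y)))
    }
    mean(abs(perms) >= abs(r) - 1e-12)
  }
  tibble(r = r, p_value = p, stars = p_stars(p), n = n)
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "NS")
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i)) |> unname()
  }))
}

#' One-way ANOVA of a trait across genotypes
#'
#' Standard one-way decomposition via [stats::aov()]. The between-groups
#' (genotype) and within-groups (error) mean squares are reported; under the
#' mean-squares heritability convention these play the roles of the genetic
#' and environmental variances (see [broad_sense_heritability()]).
#'
#' @param data A data frame.
#' @param value Column name (string) of the trait values.
#' @param group Column name (string) of the genotype labels.
#' @return An object of class `trait_anova`: list with `ms_genotype`,
#'   `ms_error`, `f`, `p_value`, `df_genotype`, `df_error`, `group_stats`
#'   (tibble of group, n, mean), and the retained `data`. When every group
#'   is an identical constant both MS are 0 and `f` is `NA` with
#'   `f_undefined = TRUE`.
#' @export
oneway_anova <- function(data, value, group) {
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  df <- tibble(value = as.numeric(data[[value]]),
               group = as.character(data[[group]]))
  df <- df[complete.cases(df), ]
  k <- length(unique(df$group))
  if (k < 2L) ct_abort("need at least 2 groups", "ct_error_single_group")
  n <- nrow(df)
  if (n - k < 1L) {
    ct_abort("no error degrees of freedom: need replicate observations within groups",
             "ct_error_no_df")
  }
  fit <- aov(value ~ factor(group), data = df)
  tab <- suppressWarnings(anova(fit))   # constant data is handled below
  msg <- tab$`Mean Sq`[1L]; mse <- tab$`Mean Sq`[2L]
  ## all-constant data: both MS vanish up to floating-point noise
  tol <- 1e-20 * (1 + mean(df$value)^2)
  undefined <- msg <= tol && mse <= tol
  if (undefined) msg <- mse <- 0
  structure(list(
    ms_genotype = msg, ms_error = mse,
    f = if (undefined) NA_real_ else tab$`F value`[1L],
    p_value = if (undefined) NA_real_ else tab$`Pr(>F)`[1L],
    f_undefined = undefined,
    df_genotype = tab$Df[1L], df_error = tab$Df[2L],
    group_stats = dplyr::summarise(dplyr::group_by(df, .data$group),
                                   n = dplyr::n(), mean = mean(.data$value),
                                   .groups = "drop"),
    data = df
  ), class = "trait_anova")
}

#' @method tidy trait_anova
#' @export
tidy.trait_anova <- function(x, ...) {
  tibble(term = c("genotype", "error"),
         df = c(x$df_genotype, x$df_error),
         meansq = c(x$ms_genotype, x$ms_error),
         statistic = c(x$f, NA_real_),
         p_value = c(x$p_value, NA_real_))
}

#' @method glance trait_anova
#' @export
glance.trait_anova <- function(x, ...) {
  tibble(ms_genotype = x$ms_genotype, ms_error = x$ms_error, f = x$f,
         p_value = x$p_value, df_genotype = x$df_genotype,
         df_error = x$df_error,
         h2 = broad_sense_heritability(x$ms_genotype, x$ms_error))
}

#' @export
print.trait_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: %d groups, F(%d, %d) = %.4g, p = %.4g\n",
              nrow(x$group_stats), x$df_genotype, x$df_error, x$f, x$p_value))
  cat(sprintf("  MS genotype = %.6g, MS error = %.6g\n",
              x$ms_genotype, x$ms_error))
  invisible(x)
}

## Tukey-Kramer pairwise p-values from the studentized range distribution;
## valid for unequal group sizes.
tukey_kramer_pairs <- function(anova) {
  gs <- anova$group_stats
  k <- nrow(gs)
  pairs <- utils::combn(k, 2L)
  se <- sqrt(anova$ms_error / 2 * (1 / gs$n[pairs[1L, ]] + 1 / gs$n[pairs[2L, ]]))
  diff <- gs$mean[pairs[1L, ]] - gs$mean[pairs[2L, ]]
  q <- abs(diff) / se
  p <- stats::ptukey(q, k, anova$df_error, lower.tail = FALSE)
  p[se == 0] <- ifelse(abs(diff[se == 0]) > 0, 0, 1)
  tibble(group1 = gs$group[pairs[1L, ]], group2 = gs$group[pairs[2L, ]],
         diff = diff, se = se, q = q, p_value = p)
}

#' Tukey-Kramer compact letter display for genotype groups
#'
#' Pairwise Tukey-Kramer comparisons (studentized range on the ANOVA error
#' mean square, valid for unequal group sizes) at level `alpha`, summarised
#' as a compact letter display via the insert-absorb procedure: groups
#' sharing a letter are not significantly different. Groups are sorted by
#' descending mean and letters are assigned alphabetically from the top.
#'
#' @param anova A `trait_anova` object from [oneway_anova()].
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `group`, `n`, `mean`, `letters`, sorted by
#'   descending mean; the pairwise table is attached as attribute `pairs`.
#' @export
tukey_letters <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "trait_anova"))
  if (anova$df_error < 1L) {
    ct_abort("no error degrees of freedom for Tukey-Kramer", "ct_error_no_df")
  }
  gs <- dplyr::arrange(anova$group_stats, dplyr::desc(.data$mean))
  k <- nrow(gs)
  pairs <- tukey_kramer_pairs(anova)
  sig <- matrix(FALSE, k, k, dimnames = list(gs$group, gs$group))
  for (i in seq_len(nrow(pairs))) {
    if (!is.na(pairs$p_value[i]) && pairs$p_value[i] < alpha) {
      sig[pairs$group1[i], pairs$group2[i]] <- TRUE
      sig[pairs$group2[i], pairs$group1[i]] <- TRUE
    }
  }
  ## insert-absorb over groups ordered by descending mean
  cols <- list(rep(TRUE, k))   # each letter column: membership flags
  for (i in seq_len(nrow(pairs))) {
    if (!sig[pairs$group1[i], pairs$group2[i]]) next
    a <- match(pairs$group1[i], gs$group)
    b <- match(pairs$group2[i], gs$group)
    new_cols <- list()
    for (col in cols) {
      if (col[a] && col[b]) {
        ca <- col; ca[b] <- FALSE
        cb <- col; cb[a] <- FALSE
        new_cols <- c(new_cols, list(ca, cb))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    ## absorb columns contained in another
    keep <- rep(TRUE, length(new_cols))
    for (u in seq_along(new_cols)) {
      for (v in seq_along(new_cols)) {
        if (u != v && keep[v] &&
            all(new_cols[[u]] <= new_cols[[v]]) &&
            !identical(new_cols[[u]], new_cols[[v]])) {
          keep[u] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  ## order columns by first member so letters run top-down
  cols <- cols[order(vapply(cols, function(cl) which(cl)[1L], 1L))]
  letters_per_group <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, `[`, TRUE, g))], collapse = "")
  }, "")
  out <- dplyr::mutate(gs, letters = letters_per_group)
  attr(out, "pairs") <- pairs
  out
}

#' Broad-sense heritability from ANOVA mean squares
#'
#' `H^2 = V_G / (V_G + V_E)`. In the mean-squares convention the genotype
#' and error mean squares are taken directly as the genetic and
#' environmental variances (`V_G = MS_G`, `V_E = MS_E`), as is common in
#' field-phenotyping reports. The variance-components alternative uses the
#' unbiased estimate `V_G = (MS_G - MS_E) / n0` for `n0` replicates per
#' genotype (truncated at 0).
#'
#' @param ms_genotype,ms_error Mean squares from a genotype ANOVA (>= 0,
#'   not both 0).
#' @param method `"mean_squares"` (default) or `"variance_components"`.
#' @param n_rep Replicates per genotype for the variance-components method.
#' @return H^2 in \[0, 1\].
#' @export
#' @examples
#' broad_sense_heritability(1, 1) # 0.5
broad_sense_heritability <- function(ms_genotype, ms_error,
                                     method = c("mean_squares", "variance_components"),
                                     n_rep = 1) {
  method <- match.arg(method)
  stopifnot(all(ms_genotype >= 0), all(ms_error >= 0))
  if (any(ms_genotype == 0 & ms_error == 0)) {
    ct_abort("both mean squares are zero", "ct_error_degenerate")
  }
  if (method == "mean_squares") {
    ms_genotype / (ms_genotype + ms_error)
  } else {
    vg <- pmax((ms_genotype - ms_error) / n_rep, 0)
    vg / (vg + ms_error)
  }
}

#' Per-date broad-sense heritability of a trait
#'
#' Applies the exclusion rule, runs a one-way genotype ANOVA per date and
#' returns the H^2 series. By default the excluded genotypes are those that
#' are the sole member of their species group (a single outgroup cultivar
#' would otherwise inflate the genotype variance). Reference lines at 0.5
#' (useful for genotype selection) and 0.7 (useful for genotype
#' differentiation) are drawn by [autoplot()].
#'
#' @param table Trait table with one row per plant per date; needs columns
#'   `plant_id`, `genotype`, `group`, a date column `date_col` and the trait.
#' @param trait Trait column name (string).
#' @param exclude Genotypes to exclude; `NULL` (default) excludes genotypes
#'   whose group contains no other genotype; `character(0)` excludes none.
#' @param date_col Name of the date/DAP column (default `"dap"`).
#' @param method Heritability convention, see [broad_sense_heritability()].
#' @return A tibble of class `heritability_series`: one row per date with
#'   `dap`, `h2`, `ms_genotype`, `ms_error`, `n_genotypes`, `n_plants`.
#' @export
heritability_pipeline <- function(table, trait, exclude = NULL,
                                  date_col = "dap",
                                  method = "mean_squares") {
  stopifnot(all(c("genotype", "group", date_col, trait) %in% names(table)))
  if (is.null(exclude)) {
    gg <- dplyr::distinct(table, .data$genotype, .data$group)
    counts <- table(gg$group)
    exclude <- gg$genotype[gg$group %in% names(counts)[counts == 1L]]
  }
  kept <- table[!(table$genotype %in% exclude), ]
  if (nrow(kept) == 0L) {
    ct_abort("all data excluded", "ct_error_all_excluded")
  }
  if (length(unique(kept$genotype)) < 2L) {
    ct_abort("fewer than 2 genotypes remain after exclusion", "ct_error_single_group")
  }
  out <- purrr::map_dfr(sort(unique(kept[[date_col]])), function(d) {
    sub <- kept[kept[[date_col]] == d, ]
    an <- oneway_anova(sub, trait, "genotype")
    tibble(dap = d,
           h2 = broad_sense_heritability(an$ms_genotype, an$ms_error,
                                         method = method,
                                         n_rep = mean(an$group_stats$n)),
           ms_genotype = an$ms_genotype, ms_error = an$ms_error,
           n_genotypes = nrow(an$group_stats), n_plants = nrow(sub))
  })
  class(out) <- c("heritability_series", class(out))
  attr(out, "trait") <- trait
  out
}

#' @method autoplot heritability_series
#' @export
autoplot.heritability_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dap, y = .data$h2)) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.7), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days after planting",
                  y = expression(H^2),
                  title = paste0("Broad-sense heritability: ",
                                 attr(object, "trait") %||% "")) +
    ggplot2::theme_minimal()
}

#' Trait-vs-yield correlation table
#'
#' Pearson correlation (with stars) between fiber yield and each trait on
#' each date, after applying the same exclusion rule as
#' [heritability_pipeline()].
#'
#' @param table Trait table (one row per plant per date) carrying
#'   `genotype`, `group`, a yield column and the traits.
#' @param traits Character vector of trait column names.
#' @param yield_col Yield column name (default `"yield_g"`).
#' @param date_col Date/DAP column name (default `"dap"`).
#' @param exclude As in [heritability_pipeline()].
#' @return A tidy tibble: `dap`, `trait`, `r`, `p_value`, `stars`, `n`.
#' @export
correlate_with_yield <- function(table, traits, yield_col = "yield_g",
                                 date_col = "dap", exclude = NULL) {
  stopifnot(all(c(traits, yield_col, date_col, "genotype", "group") %in% names(table)))
  if (is.null(exclude)) {
    gg <- dplyr::distinct(table, .data$genotype, .data$group)
    counts <- table(gg$group)
    exclude <- gg$genotype[gg$group %in% names(counts)[counts == 1L]]
  }
  kept <- table[!(table$genotype %in% exclude), ]
  grid <- tidyr::expand_grid(dap = sort(unique(kept[[date_col]])), trait = traits)
  purrr::map2_dfr(grid$dap, grid$trait, function(d, tr) {
    sub <- kept[kept[[date_col]] == d, ]
    dplyr::bind_cols(tibble(dap = d, trait = tr),
                     pearson_with_stars(sub[[tr]], sub[[yield_col]]))
  })
}
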