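#' Average observations to biological-replicate means
#'
#' Group comparisons are performed on averaged values of biological
#' replicates: each (group, replicate) cell collapses to its mean before
#' ranking, so pseudo-replicated cells do not inflate n.
#'
#' @param data A data frame.
#' @param value,group,replicate Columns (tidy-eval) holding the measurement,
#'   the group label and the biological-replicate id.
#' @return Tibble with one row per (group, replicate) and a `value` column.
#' @export
replicate_means <- function(data, value, group, replicate) {
  data |>
    dplyr::group_by({{ group }}, {{ replicate }}) |>
    dplyr::summarise(value = mean({{ value }}), .groups = "drop") |>
    dplyr::rename(group = {{ group }}, replicate = {{ replicate }})
}

prepare_groups <- function(data, value, group, replicate = NULL,
                           average_replicates = TRUE) {
  rep_q <- enquo(replicate)
  if (!quo_is_null(rep_q) && average_replicates) {
    df <- replicate_means(data, {{ value }}, {{ group }}, !!rep_q)
  } else {
    df <- dplyr::transmute(data, group = {{ group }}, value = {{ value }})
  }
  df <- dplyr::filter(df, !is.na(.data$value))
  if (any(table(df$group) == 0) || length(unique(df$group)) < 2) {
    abort("need at least two non-empty groups")
  }
  df
}

#' Kruskal–Wallis rank test across groups
#'
#' Pools all observations, ranks them with mid-ranks for ties, and computes
#' the tie-corrected Kruskal–Wallis H with a chi-square reference
#' distribution on k − 1 degrees of freedom (via [stats::kruskal.test()]).
#' When a replicate column is supplied, observations are first averaged to
#' biological-replicate means.
#'
#' @inheritParams replicate_means
#' @param replicate Optional replicate column; `NULL` analyses raw values.
#' @param average_replicates Set `FALSE` to rank raw observations even when
#'   a replicate column is present.
#' @return Tibble: `statistic` (H), `df`, `p_value`, `n_groups`, `n_obs`.
#'   All-identical data yield H = 0, p = 1.
#' @export
kruskal_wallis <- function(data, value, group, replicate = NULL,
                           average_replicates = TRUE) {
  df <- prepare_groups(data, {{ value }}, {{ group }}, {{ replicate }},
                       average_replicates)
  k <- length(unique(df$group))
  if (length(unique(df$value)) < 2) {
    return(tibble::tibble(statistic = 0, df = k - 1, p_value = 1,
                          n_groups = k, n_obs = nrow(df)))
  }
  n_obs <- nrow(df)
  kt <- stats::kruskal.test(df$value, factor(df$group))
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n_groups = k, n_obs = n_obs)
}

#' Dunn's pairwise post-hoc tests with Holm adjustment
#'
#' For every pair of groups, Dunn's z statistic from the difference in mean
#' pooled ranks with the tie-corrected variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`, two-sided
#' normal p-values, and Holm step-down adjustment across all pairs.
#'
#' @inheritParams kruskal_wallis
#' @return Tibble: `group1`, `group2`, `mean_rank_diff`, `z`, `p_value`,
#'   `p_holm`.
#' @export
dunn_holm <- function(data, value, group, replicate = NULL,
                      average_replicates = TRUE) {
  df <- prepare_groups(data, {{ value }}, {{ group }}, {{ replicate }},
                       average_replicates)
  dunn_holm_impl(split(df$value, df$group))
}

dunn_holm_impl <- function(groups) {
  k <- length(groups)
  if (k < 2) abort("need at least two groups")
  if (any(lengths(groups) == 0)) abort("empty group in Dunn's test")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    num <- mean_ranks[[i]] - mean_ranks[[j]]
    se <- sqrt(v0 * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- if (num == 0) 0 else num / se
    c(diff = num, z = z)
  })
  z <- res["z", ]
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    mean_rank_diff = unname(res["diff", ]),
    z = unname(z), p_value = unname(p),
    p_holm = unname(p.adjust(p, method = "holm"))
  )
}

#' Full non-parametric group comparison
#'
#' The reporting unit used throughout the package's statistics: a
#' Kruskal–Wallis omnibus test on biological-replicate means followed by
#' Dunn's pairwise comparisons with Holm-adjusted p-values, plus per-group
#' medians and observation counts.
#'
#' @inheritParams kruskal_wallis
#' @return A `kw_dunn` object with elements `kruskal`, `pairwise`,
#'   `summary`; supports [tidy()] (pairwise table), [glance()] (omnibus
#'   row) and `print()`.
#' @export
kw_dunn <- function(data, value, group, replicate = NULL,
                    average_replicates = TRUE) {
  df <- prepare_groups(data, {{ value }}, {{ group }}, {{ replicate }},
                       average_replicates)
  kr <- kruskal_wallis(df, .data$value, .data$group)
  pw <- dunn_holm_impl(split(df$value, df$group))
  summ <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), median = median(.data$value),
                     .groups = "drop")
  structure(list(kruskal = kr, pairwise = pw, summary = summ),
            class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value,
              x$kruskal$n_obs))
  cat("Group medians:\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("Dunn pairwise (Holm-adjusted):\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @rdname kw_dunn
#' @param x A `kw_dunn` object.
#' @param ... Unused.
#' @method tidy kw_dunn
#' @export
tidy.kw_dunn <- function(x, ...) x$pairwise

#' @rdname kw_dunn
#' @method glance kw_dunn
#' @export
glance.kw_dunn <- function(x, ...) x$kruskal
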