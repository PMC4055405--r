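# Cohort summaries and the nonparametric group comparisons: per-plant de
# novo insertion loads, category counts and shares, first-leaf
# distributions, the Steel-Dwass all-pairs rank comparison used for mPing
# copy numbers across Ping SNP groups, and the reciprocal-cross rank-sum
# comparison.

#' Build a call table from printed category counts
#'
#' Expands a named vector of per-category counts into one row per call, so
#' that reported tallies can be pushed through [summarize_cohort()].
#'
#' @param counts Named integer vector (names are categories).
#' @return Tibble with columns `plant` (NA), `locus_id`, `category`,
#'   `first_leaf` (NA).
#' @export
calls_from_counts <- function(counts) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  tibble(
    plant = NA_character_,
    locus_id = paste0("locus", seq_len(sum(counts))),
    category = rep(names(counts), times = counts),
    first_leaf = NA_character_
  )
}

#' Summarize a cohort of classified calls
#'
#' Category counts and shares (shares are over categorized calls, i.e.
#' excluding `uncategorized`/`composite` patterns), per-plant mean +/- SE of
#' the de novo load, and the first-leaf distribution of shoot- and
#' leaf-specific calls.
#'
#' @param calls Tibble with columns `category` and optionally `plant`,
#'   `first_leaf` (e.g. from [classify_calls()], de novo rows).
#' @param n_plants Number of plants in the cohort (for the per-plant mean;
#'   default: number of distinct non-missing `plant` values).
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(calls, n_plants = NULL) {
  calls <- as_tibble(calls)
  if (!"category" %in% names(calls)) abort("calls must have a `category` column")
  calls <- filter(calls, !is.na(.data$category))
  total <- nrow(calls)
  categorized <- filter(calls, !.data$category %in% c("uncategorized", "composite"))
  by_category <- calls |>
    count(.data$category, name = "n") |>
    mutate(share = if_else(.data$category %in% c("uncategorized", "composite"),
                           NA_real_, .data$n / max(nrow(categorized), 1L)))
  have_plants <- "plant" %in% names(calls) && any(!is.na(calls$plant))
  if (is.null(n_plants)) {
    n_plants <- if (have_plants) length(unique(calls$plant[!is.na(calls$plant)])) else NA_integer_
  }
  if (have_plants && !is.na(n_plants)) {
    per_plant <- calls |>
      filter(!is.na(.data$plant)) |>
      count(.data$plant, name = "n_calls")
    if (nrow(per_plant) < n_plants) {
      per_plant <- bind_rows(
        per_plant,
        tibble(plant = paste0(".empty", seq_len(n_plants - nrow(per_plant))),
               n_calls = 0L)
      )
    }
    mean_per_plant <- mean(per_plant$n_calls)
    se_per_plant <- sd(per_plant$n_calls) / sqrt(nrow(per_plant))
  } else {
    per_plant <- tibble(plant = character(), n_calls = integer())
    mean_per_plant <- NA_real_
    se_per_plant <- NA_real_
  }
  first_leaf <- if ("first_leaf" %in% names(calls)) {
    calls |>
      filter(.data$category %in% c("shoot", "leaf"), !is.na(.data$first_leaf)) |>
      count(.data$first_leaf, name = "n") |>
      mutate(share = .data$n / sum(.data$n))
  } else {
    tibble(first_leaf = character(), n = integer(), share = double())
  }
  structure(
    list(total = total, by_category = by_category, per_plant = per_plant,
         mean_per_plant = mean_per_plant, se_per_plant = se_per_plant,
         first_leaf = first_leaf, n_plants = n_plants),
    class = "cohort_summary"
  )
}

#' Combined share of a set of categories
#'
#' @param summary A `cohort_summary`.
#' @param categories Categories to pool.
#' @param percent Return nearest-integer percent (the reporting convention)
#'   instead of a fraction.
#' @return A number.
#' @export
category_share <- function(summary, categories, percent = TRUE) {
  s <- sum(summary$by_category$share[summary$by_category$category %in% categories],
           na.rm = TRUE)
  if (percent) round(100 * s) else s
}

#' Combined count of a set of categories
#'
#' @param summary A `cohort_summary`.
#' @param categories Categories to pool.
#' @return Integer count.
#' @export
category_count <- function(summary, categories) {
  sum(summary$by_category$n[summary$by_category$category %in% categories])
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$total, " de novo calls", sep = "")
  if (!is.na(x$mean_per_plant)) {
    cat(sprintf(" | %.1f +/- %.1f per plant (n = %d)",
                x$mean_per_plant, x$se_per_plant, x$n_plants))
  }
  cat("\n")
  print(x$by_category)
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$by_category

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(total = x$total, n_plants = x$n_plants,
         mean_per_plant = x$mean_per_plant, se_per_plant = x$se_per_plant)
}

# tie-corrected two-sample rank-sum z statistic (mid-ranks)
rank_sum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  v <- n1 * n2 / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (v <= 0) return(list(w = w, z = 0, var = v))
  list(w = w, z = (w - e) / sqrt(v), var = v)
}

#' Steel-Dwass all-pairs comparison
#'
#' Nonparametric all-pairs multiple comparison: for every pair of groups a
#' two-sample rank-sum statistic is computed with mid-ranks and
#' tie-corrected variance, and the studentized statistic `q = sqrt(2)|z|` is
#' referred to the studentized-range distribution with `k` groups (infinite
#' degrees of freedom), which controls the familywise error across pairs.
#' With two groups this reduces exactly to the two-sided normal
#' approximation of the Wilcoxon rank-sum test.
#'
#' An optional seeded permutation mode estimates the familywise-adjusted
#' p-values from the permutation distribution of the maximal pairwise `q`.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the values and group
#'   labels.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation mode.
#' @return An object of class `steel_dwass`; see [tidy()] for the pair
#'   table.
#' @export
steel_dwass <- function(data, value, group, method = c("asymptotic", "permutation"),
                        n_perm = 2000, seed = NULL) {
  method <- match.arg(method)
  v <- pull(data, {{ value }})
  g <- as.character(pull(data, {{ group }}))
  keep_row <- !is.na(v) & !is.na(g)
  v <- v[keep_row]; g <- g[keep_row]
  lev <- unique(g)
  k <- length(lev)
  if (k < 2) abort("need at least two groups")
  sizes <- table(g)
  if (any(sizes < 2)) abort("each group needs n >= 2")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  stat_tbl <- list_rbind(map(pairs, function(p) {
    x <- v[g == p[1]]; y <- v[g == p[2]]
    rs <- rank_sum_z(x, y)
    tibble(group1 = p[1], group2 = p[2], n1 = length(x), n2 = length(y),
           w = rs$w, z = rs$z, statistic = sqrt(2) * abs(rs$z))
  }))
  if (method == "asymptotic") {
    stat_tbl$p_value <- ptukey(stat_tbl$statistic, nmeans = k, df = Inf,
                               lower.tail = FALSE)
  } else {
    if (is.null(seed)) abort("seed is required for the permutation mode")
    set.seed(as.integer(seed))
    obs <- stat_tbl$statistic
    exceed <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      gp <- sample(g)
      qmax_contrib <- map_dbl(pairs, function(p) {
        sqrt(2) * abs(rank_sum_z(v[gp == p[1]], v[gp == p[2]])$z)
      })
      qmax <- max(qmax_contrib)
      exceed <- exceed + (qmax >= obs)
    }
    stat_tbl$p_value <- (1 + exceed) / (1 + n_perm)
  }
  structure(
    list(pairs = stat_tbl, k = k, n = length(v), method = method),
    class = "steel_dwass"
  )
}

#' @export
print.steel_dwass <- function(x, ...) {
  cat("<steel_dwass> ", x$k, " groups, n = ", x$n, " (", x$method, ")\n",
      sep = "")
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.steel_dwass <- function(x, ...) x$pairs

#' @export
glance.steel_dwass <- function(x, ...) {
  tibble(k = x$k, n = x$n, method = x$method,
         min_p_value = min(x$pairs$p_value))
}

#' Compare de novo loads between reciprocal cross directions
#'
#' Two-sided Wilcoxon rank-sum comparison (normal approximation with tie
#' correction, no continuity correction) of per-plant de novo insertion
#' counts between the two F1 directions, with per-direction means and
#' standard errors.
#'
#' @param counts_dir1,counts_dir2 Numeric vectors of per-plant counts.
#' @param labels Direction labels.
#' @return An object of class `reciprocal_test`.
#' @export
compare_reciprocal <- function(counts_dir1, counts_dir2,
                               labels = c("dir1", "dir2")) {
  if (!length(counts_dir1) || !length(counts_dir2)) {
    abort("both directions need at least one plant")
  }
  rs <- rank_sum_z(counts_dir1, counts_dir2)
  p <- if (rs$var <= 0) 1 else 2 * pnorm(abs(rs$z), lower.tail = FALSE)
  means <- tibble(
    direction = labels,
    n = c(length(counts_dir1), length(counts_dir2)),
    mean = c(mean(counts_dir1), mean(counts_dir2)),
    se = c(sd(counts_dir1) / sqrt(length(counts_dir1)),
           sd(counts_dir2) / sqrt(length(counts_dir2)))
  )
  structure(
    list(p_value = p, w = rs$w, z = rs$z, means = means),
    class = "reciprocal_test"
  )
}

#' @export
print.reciprocal_test <- function(x, ...) {
  cat(sprintf("<reciprocal_test> p = %.3g (rank-sum z = %.3f)\n", x$p_value, x$z))
  print(x$means)
  invisible(x)
}

#' @export
tidy.reciprocal_test <- function(x, ...) x$means

#' @export
glance.reciprocal_test <- function(x, ...) {
  tibble(p_value = x$p_value, z = x$z, w = x$w)
}
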