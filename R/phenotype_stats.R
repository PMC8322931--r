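# Screening statistics over the score atlas: background comparisons
# (Welch + FDR), hypercomplementation detection, rank-sum comparisons of
# structural groups, and Fisher enrichment tests.

#' Compare variant scores between genetic backgrounds
#'
#' Per (variant, concentration) Welch's t test from summary statistics
#' (combined score, regularized error converted to a replicate SD, and the
#' replicate count), two-sided, with Benjamini-Hochberg FDR applied within
#' each concentration family.
#'
#' Because the per-variant errors are regularized toward a
#' count-propagated prior (weight `nu`) and calibrated on the synonymous
#' population, each group's variance estimate carries more information
#' than its raw replicate count; `prior_df` extra degrees of freedom per
#' group credit this (moderated-statistics convention).
#'
#' @param score_table A [build_score_table()] result with both backgrounds.
#' @param backgrounds Pair of background names (reference second is
#'   subtracted from the first: direction is `bg2 - bg1` in `delta`).
#' @param alpha FDR level.
#' @param prior_df Extra per-group degrees of freedom from the error
#'   regularization (defaults to the regularization weight `nu`).
#' @return A tibble per (variant, folinate): `delta`
#'   (`score_av - score_wt`), `t`, `df_welch`, `p`, `q`, `flagged`,
#'   `direction`.
#' @export
compare_backgrounds <- function(score_table, backgrounds = c("wt", "av"),
                                alpha = 0.05, prior_df = 2) {
  wm <- dplyr::filter(score_table, .data$well_measured, .data$df >= 2L)
  a <- wm |>
    dplyr::filter(.data$background == backgrounds[1L]) |>
    dplyr::select("variant", "type", "folinate",
                  m1 = "score", se1 = "sd", n1 = "df")
  b <- wm |>
    dplyr::filter(.data$background == backgrounds[2L]) |>
    dplyr::select("variant", "folinate", m2 = "score", se2 = "sd",
                  n2 = "df")
  paired <- dplyr::inner_join(a, b, by = c("variant", "folinate"))
  abort_if(nrow(paired) == 0L, "No variants measured in both backgrounds.")
  w <- welch_summary(paired$m2, paired$se2 * sqrt(paired$n2), paired$n2,
                     paired$m1, paired$se1 * sqrt(paired$n1), paired$n1,
                     df1 = paired$n2 - 1 + prior_df,
                     df2 = paired$n1 - 1 + prior_df)
  out <- paired |>
    dplyr::mutate(
      delta = .data$m2 - .data$m1,
      t = w$t, df_welch = w$df, p = w$p
    ) |>
    dplyr::group_by(.data$folinate) |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      flagged = dplyr::coalesce(.data$q < alpha, FALSE),
      direction = dplyr::case_when(
        !.data$flagged ~ "none",
        .data$delta < 0 ~ "less_functional",
        TRUE ~ "more_functional"
      )
    )
  dplyr::select(out, "variant", "type", "folinate", "delta", "t",
                "df_welch", "p", "q", "flagged", "direction")
}

#' Summarise background-shift calls across concentrations
#'
#' @param comparisons A [compare_backgrounds()] tibble.
#' @return One-row tibble: counts of variants significantly less/more
#'   functional in the second background in at least one, and in all,
#'   tested concentrations (among variants tested at every concentration).
#' @export
summarize_background_shifts <- function(comparisons) {
  n_conc <- dplyr::n_distinct(comparisons$folinate)
  per_var <- comparisons |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      less_any = any(.data$direction == "less_functional"),
      less_all = .data$n_tested == n_conc &
        all(.data$direction == "less_functional"),
      more_any = any(.data$direction == "more_functional"),
      more_all = .data$n_tested == n_conc &
        all(.data$direction == "more_functional"),
      .groups = "drop"
    )
  tibble::tibble(
    n_variants = nrow(per_var),
    less_functional_any = sum(per_var$less_any),
    less_functional_all = sum(per_var$less_all),
    more_functional_any = sum(per_var$more_any),
    more_functional_all = sum(per_var$more_all)
  )
}

#' Identify hypercomplementing variants
#'
#' Candidates are missense variants whose base functionality exceeds 1
#' (wild-type-like); each is tested one-sided (greater) by Welch's t
#' against the pooled synonymous base-functionality distribution, with
#' Benjamini-Hochberg FDR over the candidate family.
#'
#' @param fits [fit_dose_response()] results for one background, including
#'   synonymous variants; requires a `type` column (joined from the score
#'   table if absent).
#' @param types Optional tibble `variant`, `type` when `fits` lacks `type`.
#' @param alpha FDR level.
#' @param prior_df Extra candidate-side degrees of freedom from the error
#'   regularization (see [compare_backgrounds()]).
#' @return A tibble of missense candidates with `t`, `df_welch`, `p`, `q`
#'   and `hypercomplementing`; the synonymous summary is attached as
#'   attribute `"synonymous_summary"`.
#' @export
find_hypercomplementers <- function(fits, types = NULL, alpha = 0.05,
                                    prior_df = 2) {
  if (!"type" %in% names(fits)) {
    abort_if(is.null(types), "Supply `types` when `fits` has no type column.")
    fits <- dplyr::inner_join(fits, dplyr::distinct(types), by = "variant")
  }
  fits <- dplyr::filter(fits, .data$fit_ok)
  syn <- dplyr::filter(fits, .data$type == "synonymous")
  abort_if(nrow(syn) < 2L, "Empty synonymous reference set.")
  syn_m <- mean(syn$b)
  syn_sd <- sd(syn$b)
  syn_n <- nrow(syn)

  cand <- dplyr::filter(fits, .data$type == "missense", .data$b > 1)
  w <- welch_summary(cand$b, cand$se_b * sqrt(cand$n_obs), cand$n_obs,
                     syn_m, syn_sd, syn_n, alternative = "greater",
                     df1 = cand$n_obs - 1 + prior_df, df2 = syn_n - 1)
  out <- cand |>
    dplyr::mutate(t = w$t, df_welch = w$df, p = w$p,
                  q = stats::p.adjust(.data$p, method = "BH"),
                  hypercomplementing = dplyr::coalesce(.data$q < alpha,
                                                       FALSE))
  attr(out, "synonymous_summary") <- tibble::tibble(
    mean = syn_m, sd = syn_sd, n = syn_n
  )
  out
}

#' Rank-sum comparison of two score groups
#'
#' Two-sided Mann-Whitney U test via [stats::wilcox.test()] (exact when
#' both groups are small and tie-free, normal approximation otherwise),
#' with the difference of medians reported as `group A - group B`.
#'
#' @param values_a,values_b Numeric vectors (e.g. per-position median
#'   scores of two structural groups).
#' @param exact_max Use the exact distribution when `n1 * n2` is at most
#'   this.
#' @return One-row tibble: `n_a`, `n_b`, `u`, `delta_median`, `p`.
#' @export
rank_sum_compare <- function(values_a, values_b, exact_max = 400L) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  abort_if(length(values_a) == 0L || length(values_b) == 0L,
           "Both groups must be non-empty.")
  exact <- length(values_a) * length(values_b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    n_a = length(values_a), n_b = length(values_b),
    u = unname(wt$statistic),
    delta_median = median(values_a) - median(values_b),
    p = wt$p.value
  )
}

#' Per-position median substitution scores
#'
#' @param score_table A [build_score_table()] result.
#' @param background Background to summarise.
#' @param folinate Optional concentration filter (default: pool all).
#' @return Tibble `position`, `median_score`, `n`.
#' @export
position_median_scores <- function(score_table, background = "wt",
                                   folinate = NULL) {
  df <- dplyr::filter(score_table, .data$well_measured,
                      .data$background == .env$background,
                      .data$type == "missense")
  if (!is.null(folinate)) {
    df <- dplyr::filter(df, .data$folinate == .env$folinate)
  }
  df |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(median_score = median(.data$score), n = dplyr::n(),
                     .groups = "drop")
}

#' Structural-context comparisons of position scores
#'
#' Runs the standard battery of rank-sum comparisons between annotated
#' position groups: buried (<20% ASA) vs exposed (>50% ASA) within each
#' domain, ligand-proximal (substrate, FAD, SAH) vs exposed, and
#' dimer-interface-buried positions.
#'
#' @param pos_scores A [position_median_scores()] tibble.
#' @param annotations A residue annotation table
#'   ([generate_residue_annotations()] format).
#' @return A tibble, one row per comparison, with group sizes, `u`,
#'   `delta_median` and `p`.
#' @export
compare_structural_groups <- function(pos_scores, annotations) {
  df <- dplyr::inner_join(pos_scores, annotations, by = "position")
  comparisons <- list(
    buried_vs_exposed_catalytic = list(
      a = df$domain == "catalytic" & df$asa_pct < 20,
      b = df$domain == "catalytic" & df$asa_pct > 50
    ),
    buried_vs_exposed_regulatory = list(
      a = df$domain == "regulatory" & df$asa_pct < 20,
      b = df$domain == "regulatory" & df$asa_pct > 50
    ),
    near_mthf_vs_exposed = list(
      a = df$near_mthf,
      b = df$domain == "catalytic" & df$asa_pct > 50
    ),
    near_fad_vs_exposed = list(
      a = df$near_fad,
      b = df$domain == "catalytic" & df$asa_pct > 50
    ),
    near_sah_vs_exposed = list(
      a = df$near_sah,
      b = df$domain == "regulatory" & df$asa_pct > 50
    ),
    dimer_interface_vs_surface = list(
      a = df$dimer_interface & df$asa_dimer_reduction_pct > 20,
      b = df$domain == "regulatory" & !df$dimer_interface
    )
  )
  purrr::imap_dfr(comparisons, function(sel, nm) {
    if (!any(sel$a) || !any(sel$b)) return(NULL)
    res <- rank_sum_compare(df$median_score[sel$a], df$median_score[sel$b])
    dplyr::mutate(res, comparison = nm, .before = 1L)
  })
}

#' Fisher enrichment of a variant set in an annotation class
#'
#' Exact test on the 2x2 table of set membership against annotation; the
#' conditional-MLE odds ratio from [stats::fisher.test()] and the sample
#' odds ratio `(ad)/(bc)` are both reported (zero margins give an
#' infinite/zero sample OR with a flag).
#'
#' @param in_set Logical vector over the universe.
#' @param in_annotation Logical vector over the same universe.
#' @return One-row tibble: table cells, `or_cmle`, `or_sample`, `p`,
#'   `degenerate`.
#' @export
fisher_enrichment <- function(in_set, in_annotation) {
  abort_if(length(in_set) != length(in_annotation),
           "Inputs must have equal length.")
  keep <- !is.na(in_set) & !is.na(in_annotation)
  tab <- table(factor(in_set[keep], levels = c(TRUE, FALSE)),
               factor(in_annotation[keep], levels = c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  tibble::tibble(
    set_annotated = a, set_other = b,
    rest_annotated = c_, rest_other = d,
    or_cmle = unname(ft$estimate),
    or_sample = (a * d) / (b * c_),
    p = ft$p.value,
    degenerate = degenerate
  )
}
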