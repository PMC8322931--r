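# Balanced precision-recall evaluation and diploid genotype scoring under
# models of increasing genetic-context awareness (M1-M3).

#' Balanced precision-recall evaluation of a score-based classifier
#'
#' Balanced precision at a threshold assumes a 50/50 class prior:
#' `bp(t) = sens(t) / (sens(t) + fpr(t))`. The curve is swept over all
#' score thresholds, tie-collapsed (one point per distinct recall, keeping
#' the best precision), anchored at recall 0 / precision 1, and integrated
#' by the trapezoid rule to give the AUBPRC. R90P is the maximum recall at
#' balanced precision >= 0.9.
#'
#' @param score Numeric scores.
#' @param label Logical vector: `TRUE` for the positive (pathogenic) class.
#' @param orientation `"lower_pathogenic"` (functionality scores) or
#'   `"higher_pathogenic"` (LLRp values).
#' @return An object of class `bprc_eval`: list with `curve` (tibble
#'   `recall`, `precision`), `aubprc`, `r90p`, `n_pos`, `n_neg`.
#' @export
evaluate_classifier <- function(score, label,
                                orientation = c("lower_pathogenic",
                                                "higher_pathogenic")) {
  orientation <- match.arg(orientation)
  keep <- is.finite(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  abort_if(!any(label) || all(label),
           "Both classes are required for evaluation.")
  x <- if (orientation == "lower_pathogenic") -score else score
  # predicted positive: x >= t; sweep thresholds at the observed values
  ord <- order(x, decreasing = TRUE)
  x <- x[ord]
  label <- label[ord]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  tp <- cumsum(label)
  fp <- cumsum(!label)
  last <- !duplicated(x, fromLast = TRUE)  # collapse tied scores
  sens <- tp[last] / n_pos
  fpr <- fp[last] / n_neg
  bp <- ifelse(sens + fpr == 0, 1, sens / (sens + fpr))
  curve <- tibble::tibble(recall = c(0, sens), precision = c(1, bp)) |>
    dplyr::group_by(.data$recall) |>
    dplyr::summarise(precision = max(.data$precision), .groups = "drop") |>
    dplyr::arrange(.data$recall)
  au <- sum(diff(curve$recall) *
              (head(curve$precision, -1L) + tail(curve$precision, -1L)) / 2)
  r90p <- if (any(curve$precision >= 0.9)) {
    max(curve$recall[curve$precision >= 0.9])
  } else 0
  structure(
    list(curve = curve, aubprc = au, r90p = r90p,
         n_pos = n_pos, n_neg = n_neg, orientation = orientation),
    class = "bprc_eval"
  )
}

#' @export
print.bprc_eval <- function(x, ...) {
  cat("<bprc_eval> AUBPRC = ", round(x$aubprc, 4), ", R90P = ",
      round(x$r90p, 4), " (", x$n_pos, " positives, ", x$n_neg,
      " negatives)\n", sep = "")
  invisible(x)
}

#' Paired bootstrap comparison of two classifiers
#'
#' Resamples observations (jointly for both score sets) and compares the
#' AUBPRC difference; the two-sided p value is twice the smaller tail
#' (add-one corrected).
#'
#' @param score1,score2 Score vectors over the same observations.
#' @param label Logical positive-class labels.
#' @param orientation Passed to [evaluate_classifier()].
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return One-row tibble: `aubprc1`, `aubprc2`, `delta`, `ci_lo`, `ci_hi`,
#'   `p`.
#' @export
compare_classifiers <- function(score1, score2, label,
                                orientation = "lower_pathogenic",
                                n_boot = 10000L, seed = 1L) {
  keep <- is.finite(score1) & is.finite(score2) & !is.na(label)
  score1 <- score1[keep]; score2 <- score2[keep]
  label <- as.logical(label[keep])
  base1 <- evaluate_classifier(score1, label, orientation)$aubprc
  base2 <- evaluate_classifier(score2, label, orientation)$aubprc
  n <- length(label)
  with_seed(seed + 97L, {
    delta <- purrr::map_dbl(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (!any(label[idx]) || all(label[idx])) return(NA_real_)
      evaluate_classifier(score1[idx], label[idx], orientation)$aubprc -
        evaluate_classifier(score2[idx], label[idx], orientation)$aubprc
    })
  })
  delta <- delta[!is.na(delta)]
  p <- 2 * min((1 + sum(delta <= 0)) / (1 + length(delta)),
               (1 + sum(delta >= 0)) / (1 + length(delta)))
  tibble::tibble(
    aubprc1 = base1, aubprc2 = base2, delta = base1 - base2,
    ci_lo = quantile(delta, 0.025, names = FALSE),
    ci_hi = quantile(delta, 0.975, names = FALSE),
    p = min(p, 1)
  )
}

#' Score diploid genotypes under models M1-M3
#'
#' Assigns each allele a functionality score and LLRp, then each genotype
#' the minimum (least pathogenic) LLRp of its two alleles — the recessive
#' rule. Models differ in how in-cis common polymorphisms are handled:
#' * **M1** scores the rare variant as if in the wild-type background.
#' * **M2** uses the genetic-interaction model's predicted double-mutant
#'   score for alleles carrying the common polymorphism in cis.
#' * **M3** additionally multiplies in the functionality of the in-cis
#'   second polymorphism (product rule).
#'
#' @param genotypes Case-table-like tibble (`id`, `allele1_variants`,
#'   `allele2_variants`, plus any metadata columns, e.g. `onset`).
#' @param wt_scores Tibble `hgvs_p`, `score`, `position`: the wild-type
#'   background map (or virtual map) used by M1 and for non-in-cis alleles.
#' @param wt_fits,int_fits,curve Dose-response fits, interaction fits and
#'   expectation curve used by M2/M3 for in-cis alleles.
#' @param llrp A [fit_llrp()] transform (its benign floor is used for
#'   variant-free alleles).
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param c Folinate concentration for model-based scores (ug/mL).
#' @param e429a_score Functionality score of the second polymorphism
#'   (near neutral).
#' @return `genotypes` with per-allele functionality and LLRp columns,
#'   `genotype_llrp`, and `n_unscored` alleles.
#' @export
score_genotypes <- function(genotypes, wt_scores, wt_fits = NULL,
                            int_fits = NULL, curve = NULL, llrp,
                            model = c("M2", "M1", "M3"), c = 25,
                            e429a_score = 0.95) {
  model <- match.arg(model)
  if (model %in% c("M2", "M3")) {
    abort_if(is.null(wt_fits) || is.null(int_fits) || is.null(curve),
             "M2/M3 require wt_fits, int_fits and curve.")
  }

  hgvs_map <- parse_protein_variant(wt_scores$hgvs_p)
  wt_tab <- dplyr::mutate(wt_scores, variant = hgvs_map$variant)

  score_allele <- function(allele_str) {
    a <- parse_allele_string(allele_str)
    out <- tibble::tibble(func = rep(NA_real_, nrow(a)),
                          llrp_val = NA_real_, scorable = TRUE)
    no_rare <- is.na(a$rare_hgvs)
    out$llrp_val[no_rare] <- llrp$benign_floor
    out$func[no_rare] <- 1

    idx <- which(!no_rare)
    if (length(idx) > 0L) {
      parsed <- parse_protein_variant(a$rare_hgvs[idx])
      m <- match(a$rare_hgvs[idx], wt_tab$hgvs_p)
      func <- wt_tab$score[m]
      if (model %in% c("M2", "M3")) {
        in_cis <- a$a222v[idx]
        vkeys <- parsed$variant
        fits <- dplyr::left_join(
          tibble::tibble(variant = vkeys),
          dplyr::select(wt_fits, "variant", "b", "r"), by = "variant"
        )
        ints <- dplyr::left_join(
          tibble::tibble(variant = vkeys),
          dplyr::select(int_fits, "variant", "eps_b", "eps_r"),
          by = "variant"
        )
        dm <- predict(curve, fits$b + fits$r * c) +
          ints$eps_b + ints$eps_r * c
        func <- ifelse(in_cis, dm, func)
      }
      if (model == "M3") {
        func <- ifelse(a$e429a[idx], func * e429a_score, func)
      }
      out$func[idx] <- func
      out$llrp_val[idx] <- predict(llrp, func, parsed$position)
      out$scorable[idx] <- is.finite(out$llrp_val[idx])
    }
    out
  }

  a1 <- score_allele(genotypes$allele1_variants)
  a2 <- score_allele(genotypes$allele2_variants)
  dplyr::mutate(genotypes,
    model = model,
    allele1_func = a1$func, allele2_func = a2$func,
    allele1_llrp = a1$llrp_val, allele2_llrp = a2$llrp_val,
    genotype_llrp = pmin(a1$llrp_val, a2$llrp_val),
    n_unscored = as.integer(!a1$scorable) + as.integer(!a2$scorable)
  )
}
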