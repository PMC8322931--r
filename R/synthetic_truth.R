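# Ground-truth generator: per-variant true functionality, folinate response
# slopes and genetic-interaction terms with the common hypomorphic
# polymorphism (p.Ala222Val), plus residue-level structural annotations.

#' Parameters for the ground-truth generator
#'
#' Defaults emulate the study conditions of the MTHFR complementation atlas:
#' bimodal missense functionality, ~7% folinate-responsive variants
#' (preferentially hypomorphs), ~33% genetic interactions with p.Ala222Val
#' of which roughly one in six is folinate-dependent, and a small set of
#' planted suppressors and hypercomplementers. Slope magnitudes
#' (0.0015-0.003 score units per ug/mL) bracket the published example fits
#' for folinate-remediable variants.
#'
#' @param mixture_weights Named weights (`null`, `hypomorph`, `wt_like`,
#'   `hyper`) for the missense functionality mixture; must sum to 1.
#' @param wt_like_sd SD of true scores within the wild-type-like class
#'   (0 gives a strict null where every wild-type-like variant sits at 1).
#' @param responsive_fraction Overall fraction of missense variants with a
#'   nonzero folinate slope.
#' @param hypomorph_bias Relative odds that a responsive slope lands on a
#'   hypomorph rather than another class.
#' @param negative_slope_prob Probability that a responsive slope is negative
#'   (only assigned where the score stays in range).
#' @param slope_range Magnitude range for folinate slopes (score per ug/mL).
#' @param interaction_fraction Overall fraction of missense variants with a
#'   genetic interaction.
#' @param dependent_share Share of interacting variants whose interaction is
#'   folinate-dependent.
#' @param negative_interaction_prob Probability an interaction is negative.
#' @param gamma_b_range Magnitude range of folinate-independent interactions.
#' @param gamma_r_range Magnitude range of folinate-dependent interactions
#'   (score per ug/mL).
#' @param suppressor_fraction Fraction of missense variants planted as
#'   dedicated suppressors of the common polymorphism.
#' @param suppressor_split Named shares (`independent`, `low_folinate`,
#'   `high_folinate`) of the planted suppressor categories.
#' @param suppressor_threshold True double-mutant score above which an
#'   allele exceeds polymorphism-like functionality (the truth-side
#'   analogue of the 95th-percentile synonymous threshold).
#' @param eval_folinate Concentrations at which suppressor labels are
#'   evaluated.
#' @param w_max Upper clip for true scores.
#' @return A named list of parameters.
#' @export
ground_truth_params <- function(
    mixture_weights = c(null = 0.30, hypomorph = 0.15,
                        wt_like = 0.50, hyper = 0.05),
    wt_like_sd = 0.05,
    responsive_fraction = 0.07,
    hypomorph_bias = 6,
    negative_slope_prob = 0.15,
    slope_range = c(0.0015, 0.003),
    interaction_fraction = 0.33,
    dependent_share = 521 / 3359,
    negative_interaction_prob = 0.75,
    gamma_b_range = c(0.2, 0.5),
    gamma_r_range = c(0.002, 0.005),
    suppressor_fraction = 0.04,
    suppressor_split = c(independent = 0.4, low_folinate = 0.5,
                         high_folinate = 0.1),
    suppressor_threshold = 1.15,
    eval_folinate = c(12.5, 25, 100, 200),
    w_max = 1.6) {
  abort_if(abs(sum(mixture_weights) - 1) > 1e-8,
           "`mixture_weights` must sum to 1.")
  as.list(environment())
}

#' Generate residue-level structural annotations
#'
#' Produces a synthetic per-position annotation table in the format consumed
#' downstream: domain labels (serine-rich, catalytic, linker, regulatory),
#' accessible surface area, ligand-proximity flags (substrate/folate, FAD,
#' SAH) and dimer-interface membership. Deterministic given `seed`.
#'
#' @param cds A [coding_sequence()].
#' @param seed Integer seed.
#' @param catalytic_end,linker_end Last positions of the catalytic domain and
#'   linker (serine-rich region ends at position 37).
#' @return A tibble with columns `position`, `domain`, `asa_pct`,
#'   `asa_dimer_reduction_pct`, `near_mthf`, `near_fad`, `near_sah`,
#'   `dimer_interface`.
#' @export
generate_residue_annotations <- function(cds, seed = 1L,
                                         catalytic_end = 356L,
                                         linker_end = 363L) {
  n <- nchar(cds$protein)
  with_seed(seed + 7L, {
    domain <- dplyr::case_when(
      seq_len(n) <= 37L ~ "serine_rich",
      seq_len(n) <= catalytic_end ~ "catalytic",
      seq_len(n) <= linker_end ~ "linker",
      TRUE ~ "regulatory"
    )
    asa <- 100 * rbeta(n, 1.2, 1.5)
    catalytic <- which(domain == "catalytic")
    regulatory <- which(domain == "regulatory")
    # ligand pockets are buried: bias proximity flags to low-ASA residues
    pocket_weight <- function(idx) (100 - asa[idx])^2
    near_mthf <- sample(catalytic, 18L, prob = pocket_weight(catalytic))
    near_fad <- sample(catalytic, 22L, prob = pocket_weight(catalytic))
    near_sah <- sample(regulatory, 20L, prob = pocket_weight(regulatory))
    dimer <- sample(regulatory, 28L)
    tibble::tibble(
      position = seq_len(n),
      domain = domain,
      asa_pct = asa,
      asa_dimer_reduction_pct = ifelse(seq_len(n) %in% dimer,
                                       runif(n, 20, 60), runif(n, 0, 15)),
      near_mthf = seq_len(n) %in% near_mthf,
      near_fad = seq_len(n) %in% near_fad,
      near_sah = seq_len(n) %in% near_sah,
      dimer_interface = seq_len(n) %in% dimer
    )
  })
}

#' Sample a ground truth for every mutational outcome
#'
#' Draws true base functionality (`w_base`, score units: 0 = null, 1 =
#' wild-type-like), folinate slopes (`rho`), and genetic-interaction terms
#' (`gamma_b`, `gamma_r`) for all `21 x L` outcomes of a coding sequence.
#' Nonsense outcomes are anchored at `w_base = 0`, synonymous at
#' `w_base = 1`, both with zero slopes. When `annotations` are supplied,
#' buried or ligand-proximal catalytic positions are biased toward loss of
#' function and SAH-pocket regulatory positions toward hypercomplementation,
#' so the structural screens have a planted signal to recover.
#'
#' @param cds A [coding_sequence()].
#' @param params A [ground_truth_params()] list.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param annotations Optional [generate_residue_annotations()] table.
#' @return A tibble, one row per outcome, with the truth columns
#'   `w_base`, `rho`, `gamma_b`, `gamma_r`, `class`, `responsive`,
#'   `interacting`, `suppressor_type`.
#' @export
sample_ground_truth <- function(cds, params = ground_truth_params(),
                                seed = 1L, annotations = NULL) {
  truth <- enumerate_outcomes(cds)
  n <- nrow(truth)
  p <- params
  with_seed(seed + 11L, {
    # --- class mixture, optionally reweighted by structural context -------
    wts <- matrix(rep(p$mixture_weights[c("null", "hypomorph", "wt_like",
                                          "hyper")],
                      each = n), nrow = n)
    colnames(wts) <- c("null", "hypomorph", "wt_like", "hyper")
    if (!is.null(annotations)) {
      ann <- annotations[match(truth$position, annotations$position), ]
      sensitive <- ann$domain == "catalytic" &
        (ann$asa_pct < 20 | ann$near_mthf | ann$near_fad)
      wts[sensitive, "null"] <- wts[sensitive, "null"] * 2.5
      # loss of SAM-mediated inhibition: hypercomplementation concentrates
      # in the regulatory domain, strongest around the SAM/SAH pocket
      regulatory <- ann$domain == "regulatory"
      wts[regulatory, "hyper"] <- wts[regulatory, "hyper"] * 2.5
      sam_pocket <- regulatory & ann$near_sah
      wts[sam_pocket, "hyper"] <- wts[sam_pocket, "hyper"] * 2
    }
    wts <- wts / rowSums(wts)
    u <- runif(n)
    cum <- t(apply(wts, 1L, cumsum))
    class <- colnames(wts)[1L + (u > cum[, 1L]) + (u > cum[, 2L]) +
                             (u > cum[, 3L])]

    w <- dplyr::case_when(
      class == "null" ~ pmin(pmax(abs(rnorm(n, 0.02, 0.03)), 0), 0.12),
      class == "hypomorph" ~ runif(n, 0.2, 0.8),
      class == "wt_like" ~ rnorm(n, 1, p$wt_like_sd),
      TRUE ~ runif(n, 1.2, 1.5)
    )

    # --- folinate response slopes, biased toward hypomorphs ---------------
    bias <- ifelse(class == "hypomorph", p$hypomorph_bias, 1)
    mean_bias <- sum(p$mixture_weights * ifelse(
      names(p$mixture_weights) == "hypomorph", p$hypomorph_bias, 1))
    p_resp <- pmin(p$responsive_fraction * bias / mean_bias, 1)
    responsive <- runif(n) < p_resp
    rho_mag <- runif(n, p$slope_range[1L], p$slope_range[2L])
    rho_sign <- ifelse(runif(n) < p$negative_slope_prob, -1, 1)
    # negative slopes only where the score stays positive across the range
    rho_sign[w < 0.6] <- 1
    rho <- ifelse(responsive, rho_sign * rho_mag, 0)
    # keep w + rho * 200 inside [0, w_max]
    rho <- pmin(rho, (p$w_max - w) / 200)
    rho <- pmax(rho, -w / 200)

    # --- genetic interactions with the common polymorphism ----------------
    interacting <- runif(n) < p$interaction_fraction
    dependent <- interacting & (runif(n) < p$dependent_share)
    g_sign <- ifelse(runif(n) < p$negative_interaction_prob, -1, 1)
    gb <- ifelse(interacting & !dependent,
                 g_sign * runif(n, p$gamma_b_range[1L], p$gamma_b_range[2L]),
                 0)
    gr <- ifelse(dependent,
                 g_sign * runif(n, p$gamma_r_range[1L], p$gamma_r_range[2L]),
                 0)
    # keep the AV-background score in range at both ends of the gradient
    gb <- pmax(gb, -(w + pmin(rho * 12.5, rho * 200)))
    gr <- pmax(gr, -(w + gb) / 200)
    gr <- pmin(gr, (p$w_max - w - gb) / 200)

    # --- planted suppressors ----------------------------------------------
    miss <- truth$type == "missense"
    cand <- which(miss)
    n_sup <- round(p$suppressor_fraction * length(cand))
    sup_idx <- sample(cand, n_sup)
    split <- p$suppressor_split / sum(p$suppressor_split)
    kind <- sample(names(split), n_sup, replace = TRUE, prob = split)
    # target AV-background trajectories per category (relative to the
    # synonymous level in the AV background, which sits at 1)
    lo <- min(p$eval_folinate)
    hi <- max(p$eval_folinate)
    for (i in seq_along(sup_idx)) {
      j <- sup_idx[i]
      targ <- switch(kind[i],
        independent = {
          s <- runif(1, 1.3, 1.5)
          c(s, s)
        },
        low_folinate = c(runif(1, 1.3, 1.5), runif(1, 0.5, 0.9)),
        high_folinate = c(runif(1, 0.7, 0.95), runif(1, 1.3, 1.5))
      )
      slope <- (targ[2L] - targ[1L]) / (hi - lo)
      base <- targ[1L] - slope * lo
      gb[j] <- base - w[j]
      gr[j] <- slope - rho[j]
    }
    interacting[sup_idx] <- TRUE

    # --- anchors ------------------------------------------------------------
    nonsense <- truth$type == "nonsense"
    synonymous <- truth$type == "synonymous"
    w[nonsense] <- 0
    w[synonymous] <- 1
    fixed <- nonsense | synonymous
    rho[fixed] <- 0
    gb[fixed] <- 0
    gr[fixed] <- 0
    responsive[fixed] <- FALSE
    interacting[fixed] <- FALSE
    class[nonsense] <- "nonsense"
    class[synonymous] <- "synonymous"
    responsive[rho == 0] <- FALSE

    # --- definitional suppressor labels -----------------------------------
    # a variant suppresses the polymorphism when it interacts positively
    # and its true double-mutant score exceeds the threshold; the category
    # follows the concentrations at which it does so
    s_av_at <- vapply(p$eval_folinate, function(cc) {
      pmin(pmax(w + rho * cc + gb + gr * cc, 0), p$w_max)
    }, numeric(n))
    above <- s_av_at > p$suppressor_threshold
    pos_int <- (gb > 1e-9 | gr > 1e-9) & miss
    lo_i <- which.min(p$eval_folinate)
    hi_i <- which.max(p$eval_folinate)
    suppressor_type <- dplyr::case_when(
      pos_int & rowSums(above) == length(p$eval_folinate) ~ "independent",
      pos_int & above[, lo_i] ~ "low_folinate",
      pos_int & above[, hi_i] ~ "high_folinate",
      TRUE ~ "none"
    )
    interacting <- interacting | suppressor_type != "none"

    dplyr::mutate(truth,
      w_base = w, rho = rho, gamma_b = gb, gamma_r = gr,
      class = class, responsive = responsive, interacting = interacting,
      suppressor_type = suppressor_type
    )
  })
}

#' True score of a variant at a folinate concentration
#'
#' Evaluates the planted truth on the score scale: in the wild-type
#' background `w_base + rho * c`, in the polymorphism background additionally
#' `gamma_b + gamma_r * c`; clipped to `[0, w_max]`.
#'
#' @param truth A [sample_ground_truth()] tibble (or subset of rows).
#' @param background `"wt"` or `"av"`.
#' @param folinate Concentration in ug/mL (scalar or vector of length
#'   `nrow(truth)`).
#' @param w_max Upper clip.
#' @return Numeric vector of true scores.
#' @export
true_score <- function(truth, background, folinate, w_max = 1.6) {
  s <- truth$w_base + truth$rho * folinate
  if (background == "av") {
    s <- s + truth$gamma_b + truth$gamma_r * folinate
  }
  pmin(pmax(s, 0), w_max)
}
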