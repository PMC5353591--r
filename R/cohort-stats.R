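metric_names <- function() c("V20", "MLD", "Q_V20", "Q_MLD", "V_V20", "V_MLD")

metric_family <- function(metric) {
  dplyr::case_when(
    metric %in% c("V20", "MLD") ~ "CT",
    metric %in% c("Q_V20", "Q_MLD") ~ "Q",
    metric %in% c("V_V20", "V_MLD") ~ "V"
  )
}

#' Binarize a toxicity grade into the RILT event indicator
#'
#' Radiation-induced lung toxicity is graded 0-5 (CTCAE v4.0); the event
#' of interest is grade >= 2, so grades 0-1 map to 0 (non-RILT) and
#' grades 2-5 to 1 (RILT). Vectorized.
#'
#' @param grade integer vector with values in 0..5.
#' @return integer vector of 0/1.
#' @examples
#' rilt_event(c(0, 1, 2, 3))
#' @export
rilt_event <- function(grade) {
  if (any(is.na(grade)) || any(grade != as.integer(grade)) ||
      any(grade < 0 | grade > 5)) {
    abort("`grade` must be integers in 0..5.")
  }
  as.integer(grade >= 2)
}

#' Tie-corrected Spearman rank correlation
#'
#' Ranks both vectors with average ranks for ties and returns the Pearson
#' correlation of the rank vectors -- the tie-corrected Spearman
#' coefficient. The two-sided p-value comes either from the t
#' approximation, t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom, or from a permutation test: y is permuted `n_perm` times and
#' p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1).
#'
#' @param x,y numeric vectors of equal length >= 3, each with at least two
#'   distinct values.
#' @param p_method `"t_approx"` (default) or `"permutation"`.
#' @param n_perm number of permutations when `p_method = "permutation"`.
#' @param seed integer seed for the permutation draw (required for that
#'   method; there is no hidden global seed).
#' @return An object of class `fl_spearman`: list with `r`, `p`, `n`,
#'   `p_method`. Use [tidy()] for a one-row tibble.
#' @examples
#' s <- spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' tidy(s)
#' @export
spearman_cor <- function(x, y, p_method = c("t_approx", "permutation"),
                         n_perm = 10000, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported.")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("constant vector: Spearman correlation undefined.")
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (p_method == "t_approx") {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  } else {
    if (is.null(seed)) abort("permutation p-values require an explicit `seed`.")
    r_perm <- local_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) stats::cor(rx, sample(ry)),
             numeric(1))
    })
    p <- (1 + sum(abs(r_perm) >= abs(r))) / (n_perm + 1)
  }
  structure(list(r = r, p = p, n = n, p_method = p_method),
            class = "fl_spearman")
}

#' @export
print.fl_spearman <- function(x, ...) {
  cat("Spearman rank correlation: r = ", signif(x$r, 3),
      ", p = ", signif(x$p, 3), " (", x$p_method, "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

# evaluate code with a local, restored RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

stratifier_levels <- function(cohort, stratifier) {
  switch(stratifier,
    copd = list(values = cohort$copd, levels = c(yes = "COPD", no = "Non-COPD")),
    pft = list(values = cohort$pft, levels = c(worse = "Worse PFT", good = "Good PFT")),
    location = list(values = cohort$location,
                    levels = c(central = "Central-type", peripheral = "Peripheral-type")),
    stage = list(values = ifelse(cohort$stage %in% c("I", "II"), "I-II", "III"),
                 levels = c(`I-II` = "Stage I-II", III = "Stage III")),
    abort(paste0("unknown stratifier: ", stratifier))
  )
}

#' Spearman correlations of each metric with RILT, overall and by subgroup
#'
#' For the whole cohort and each level of each stratifier, correlates each
#' of the six dosimetric metrics with the binary RILT event (grade >= 2)
#' and attaches a dominance label per stratum summarizing how the three
#' metric families (CT anatomical, Q perfusion, V ventilation) rank.
#' Strata where the correlation is undefined (fewer than 3 patients or a
#' constant outcome) are reported with `computable = FALSE`, never
#' silently dropped. Set `outcome = "grade"` to correlate against the
#' ordinal grade instead of the binary event.
#'
#' @param cohort tibble with the six metric columns plus `rilt_grade` and
#'   the stratifier columns (`copd`, `pft`, `location`, `stage`).
#' @param strata character vector of stratifier names; default the four
#'   clinical stratifiers.
#' @param epsilon half-width within which two family |r| values are
#'   considered equivalent in the dominance label; default 0.05.
#' @param outcome `"event"` (default, grade >= 2) or `"grade"` (ordinal).
#' @inheritParams spearman_cor
#' @return A tibble of class `fl_subgroup_table` with columns `subgroup`,
#'   `metric`, `family`, `r`, `p`, `n`, `computable`, `dominance`.
#' @export
subgroup_correlations <- function(cohort,
                                  strata = c("copd", "pft", "location", "stage"),
                                  epsilon = 0.05,
                                  outcome = c("event", "grade"),
                                  p_method = c("t_approx", "permutation"),
                                  n_perm = 10000, seed = NULL) {
  outcome <- match.arg(outcome)
  p_method <- match.arg(p_method)
  if (nrow(cohort) == 0) abort("empty cohort.")
  y_all <- if (outcome == "event") rilt_event(cohort$rilt_grade) else cohort$rilt_grade

  groups <- list(list(label = "All patients", idx = rep(TRUE, nrow(cohort))))
  for (s in strata) {
    sl <- stratifier_levels(cohort, s)
    for (lv in names(sl$levels)) {
      groups <- c(groups, list(list(label = unname(sl$levels[lv]),
                                    idx = sl$values == lv)))
    }
  }

  rows <- map_dfr(groups, function(g) {
    y <- y_all[g$idx]
    map_dfr(metric_names(), function(m) {
      xv <- cohort[[m]][g$idx]
      ok <- length(y) >= 3 && length(unique(y)) >= 2 && length(unique(xv)) >= 2
      if (ok) {
        sc <- spearman_cor(xv, y, p_method = p_method, n_perm = n_perm, seed = seed)
        tibble(subgroup = g$label, metric = m, r = sc$r, p = sc$p,
               n = sc$n, computable = TRUE)
      } else {
        tibble(subgroup = g$label, metric = m, r = NA_real_, p = NA_real_,
               n = length(y), computable = FALSE)
      }
    })
  })
  rows$family <- metric_family(rows$metric)
  lab <- rows |>
    group_by(.data$subgroup) |>
    summarise(dominance = dominance_label_impl(.data$family, .data$r,
                                               .data$computable, epsilon),
              .groups = "drop")
  out <- left_join(rows, lab, by = "subgroup") |>
    select("subgroup", "metric", "family", "r", "p", "n", "computable", "dominance")
  class(out) <- c("fl_subgroup_table", class(out))
  out
}

dominance_label_impl <- function(family, r, computable, epsilon) {
  if (any(!computable)) return("n/a")
  fam <- vapply(c(V = "V", Q = "Q", CT = "CT"),
                function(f) mean(abs(r[family == f])), numeric(1))
  # descending |r|; exact ties broken in the fixed order V, Q, CT
  ord <- order(-fam, seq_along(fam))
  lab <- names(fam)[ord[1]]
  for (i in 2:3) {
    sep <- if (fam[ord[i - 1]] - fam[ord[i]] <= epsilon) "\u0020\u2248\u0020" else " > "
    lab <- paste0(lab, sep, names(fam)[ord[i]])
  }
  lab
}

#' Dominance label for one stratum's six correlation results
#'
#' Summarizes each metric family by the mean |r| of its two metrics
#' (CT: V20 + MLD; Q: Q_V20 + Q_MLD; V: V_V20 + V_MLD), sorts the three
#' families by descending mean |r| and joins adjacent families whose
#' difference is within `epsilon` with an equivalence sign, otherwise
#' with ">". Exact ties keep the fixed order V, Q, CT. Any
#' non-computable constituent yields `"n/a"`.
#'
#' @param results tibble with columns `metric`, `r` and optionally
#'   `computable` for exactly the six metrics of one stratum.
#' @param epsilon equivalence half-width on mean |r|; default 0.05.
#' @return A single label string such as `"V \u2248 Q > CT"` (with a Unicode approx sign).
#' @export
dominance_label <- function(results, epsilon = 0.05) {
  if (!all(metric_names() %in% results$metric) || nrow(results) != 6) {
    abort("`results` must contain exactly the six metrics of one stratum.")
  }
  if (epsilon <= 0) abort("`epsilon` must be > 0.")
  computable <- if ("computable" %in% names(results)) results$computable else !is.na(results$r)
  dominance_label_impl(metric_family(results$metric), results$r, computable, epsilon)
}

covariate_names <- function() {
  c("sex", "age_group", "histology", "stage", "location", "copd", "pft", "chemo")
}

#' Baseline-characteristic comparison between RILT and non-RILT patients
#'
#' For each categorical covariate, cross-tabulates the RILT event (grade
#' >= 2) against the covariate levels and tests for association: a
#' chi-square test (with continuity correction for 2x2 tables), switching
#' to Fisher's exact test for 2x2 tables with any expected cell count
#' below 5. Wider tables with small expected counts keep the chi-square
#' p-value but are flagged. Covariates with a single observed level are
#' flagged not-computable.
#'
#' @param cohort tibble with `rilt_grade` and the covariate columns.
#' @param covariates character vector; defaults to the eight baseline
#'   characteristics.
#' @param holm also report Holm-adjusted p-values; default `FALSE` (no
#'   multiplicity correction is applied by default).
#' @return A tibble of class `fl_characteristics` with columns
#'   `covariate`, `test`, `p_value`, `small_sample`, `computable` (and
#'   `p_holm` when `holm = TRUE`).
#' @export
compare_characteristics <- function(cohort, covariates = covariate_names(),
                                    holm = FALSE) {
  ev <- rilt_event(cohort$rilt_grade)
  if (length(unique(ev)) < 2) abort("both outcome groups must be non-empty.")
  out <- map_dfr(covariates, function(cv) {
    x <- cohort[[cv]]
    if (is.null(x)) abort(paste0("covariate not found: ", cv))
    if (length(unique(x)) < 2) {
      return(tibble(covariate = cv, test = NA_character_, p_value = NA_real_,
                    small_sample = FALSE, computable = FALSE))
    }
    tab <- table(ev, x)
    exp_counts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
    small <- any(exp_counts < 5)
    if (small && all(dim(tab) == c(2, 2))) {
      tibble(covariate = cv, test = "fisher",
             p_value = stats::fisher.test(tab)$p.value,
             small_sample = TRUE, computable = TRUE)
    } else {
      correct <- all(dim(tab) == c(2, 2))
      p <- suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
      tibble(covariate = cv, test = if (correct) "chisq_yates" else "chisq",
             p_value = p, small_sample = small, computable = TRUE)
    }
  })
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  class(out) <- c("fl_characteristics", class(out))
  out
}
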