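#' Normalised Shannon-entropy travel-mode diversity
#'
#' Diversity of travel modes in an area, computed over the counts of the
#' three mode groups (walking/cycling only, car users, public transport
#' users) among travellers:
#' \deqn{D = -\sum_k p_k \ln p_k / \ln N}
#' with \eqn{p_k} the share of group \eqn{k} and \eqn{N} the number of
#' groups, using the convention \eqn{0 \ln 0 = 0}. The score is 0 when one
#' mode dominates completely and 1 when all modes are equally represented.
#'
#' @param counts non-negative numeric vector of group counts (or shares);
#'   length at least 2, typically 3.
#' @return score in \[0, 1\], or `NA` when all counts are zero (undefined).
#' @examples
#' diversity_entropy(c(10, 10, 10))  # 1
#' diversity_entropy(c(30, 0, 0))    # 0
#' @export
diversity_entropy <- function(counts) {
  if (length(counts) < 2L)
    stop("at least two mode groups are required", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  p <- counts / total
  terms <- ifelse(p > 0, p * log(p), 0)
  score <- -sum(terms) / log(length(counts))
  if (score == 0) 0 else score  # entropy is non-negative; avoid -0
}

#' Aggregate classified participants into area profiles
#'
#' Builds one profile row per area from a classified survey table: duration
#' category percentages (over all participants), the PST percentage,
#' covariate percentages, travel-mode diversity (over travellers in the
#' three mode groups), and the attached outcome rate and deprivation index.
#'
#' @param classified output of [classify_travel()]; logical attribute
#'   columns `male`, `age_65plus`, `worker`, `hh_children`, `low_income`
#'   are summarised as percentages when present.
#' @param outcomes optional data frame `area_id`, `outcome_rate` (the
#'   age-standardised high-waist-circumference rate, %). Areas without an
#'   outcome are kept with `NA` and reported with a warning.
#' @param irsd optional data frame `area_id`, `irsd` with the
#'   (population-weighted) deprivation score per area.
#' @return data frame of area profiles, one row per area, with counts
#'   `n_participants`, `n_travellers` (participants in the three mode
#'   groups), percentage columns, `diversity`, `irsd`, `outcome_rate`.
#' @export
aggregate_areas <- function(classified, outcomes = NULL, irsd = NULL) {
  stopifnot(nrow(classified) > 0L)
  pct <- function(x) 100 * mean(x)
  covmap <- c(male = "pct_men", age_65plus = "pct_65plus",
              worker = "pct_workers", hh_children = "pct_hh_children",
              low_income = "pct_low_income")
  rows <- lapply(split(classified, classified$area_id), function(d) {
    dc <- d$duration_category
    grp <- d$mode_group
    gcounts <- c(sum(grp == "WALK_CYCLE_ONLY"), sum(grp == "CAR_USER"),
                 sum(grp == "PT_USER"))
    out <- data.frame(
      area_id = d$area_id[1L],
      n_participants = nrow(d),
      n_travellers = sum(gcounts),
      pct_low_at = pct(dc == "LOW_AT"),
      pct_high_at = pct(dc == "HIGH_AT"),
      pct_mt = pct(dc == "MT"),
      pct_st = pct(dc == "ST"),
      pct_pst = pct(d$pst_flag),
      pct_no_travel = pct(dc == "NO_TRAVEL"),
      diversity = diversity_entropy(gcounts))
    for (a in names(covmap))
      if (a %in% names(d)) out[[covmap[[a]]]] <- pct(d[[a]])
    out
  })
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  if (!is.null(irsd))
    profiles$irsd <- irsd$irsd[match(profiles$area_id, irsd$area_id)]
  if (!is.null(outcomes)) {
    profiles$outcome_rate <-
      outcomes$outcome_rate[match(profiles$area_id, outcomes$area_id)]
    miss <- profiles$area_id[is.na(profiles$outcome_rate)]
    if (length(miss) > 0L)
      warning("no outcome rate for area(s): ",
              paste(miss, collapse = ", "), call. = FALSE)
  }
  profiles
}

#' Apply the minimum-sample filters to area profiles
#'
#' Areas with fewer than `min_n` participants are excluded from analysis.
#' Among the included areas, the diversity score is additionally set to
#' missing where fewer than `min_n` participants travelled, since a mode-mix
#' estimate from a smaller base is unreliable; such areas stay in the
#' duration-category models and drop out of diversity models only.
#'
#' @param profiles area-profile data frame from [aggregate_areas()].
#' @param min_n minimum participant count (default 30).
#' @return list with data frames `included` and `excluded`.
#' @export
filter_areas <- function(profiles, min_n = 30) {
  keep <- profiles$n_participants >= min_n
  included <- profiles[keep, , drop = FALSE]
  if (nrow(included) > 0L && "diversity" %in% names(included))
    included$diversity[included$n_travellers < min_n] <- NA_real_
  list(included = included, excluded = profiles[!keep, , drop = FALSE])
}

#' Population-weighted deprivation score
#'
#' Aggregates sub-area socio-economic index scores (e.g. SA2-level IRSD) to
#' one area score using population weights \eqn{w_i = pop_i / \sum pop}.
#'
#' @param subarea_scores numeric scores of the constituent sub-areas.
#' @param populations positive populations of the same sub-areas.
#' @return the weighted average score.
#' @examples
#' weighted_irsd(c(900, 1100), c(3, 1))  # 950
#' @export
weighted_irsd <- function(subarea_scores, populations) {
  if (length(subarea_scores) != length(populations))
    stop("scores and populations must have equal length", call. = FALSE)
  if (any(populations <= 0))
    stop("populations must be positive", call. = FALSE)
  sum(subarea_scores * populations) / sum(populations)
}

#' Pearson correlations between travel metrics and the outcome
#'
#' Pairwise-complete Pearson correlation matrix over the travel behaviour
#' metrics, diversity and the outcome rate; areas with missing diversity
#' contribute to all other pairs.
#'
#' @param profiles included area profiles.
#' @param vars columns to correlate; defaults to the metric, diversity and
#'   outcome columns present.
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   columns yield `NA` entries with a warning.
#' @export
correlation_table <- function(profiles,
                              vars = intersect(
                                c("pct_low_at", "pct_high_at", "pct_mt",
                                  "pct_st", "pct_pst", "pct_no_travel",
                                  "diversity", "outcome_rate"),
                                names(profiles))) {
  if (nrow(profiles) < 3L)
    stop("at least 3 areas are required for correlations", call. = FALSE)
  x <- as.matrix(profiles[, vars, drop = FALSE])
  degenerate <- vapply(vars, function(v) {
    xi <- x[, v]
    var(xi[!is.na(xi)]) == 0
  }, logical(1L))
  if (any(degenerate))
    warning("zero-variance column(s): ",
            paste(vars[degenerate], collapse = ", "), call. = FALSE)
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r) <- ifelse(degenerate, NA_real_, 1)
  r
}
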