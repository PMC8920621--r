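# Clinical evaluation calculus for psoriasis treatment studies: PASI scores
# over four body regions, before/after deltas, itching scale, efficacy
# categories, total effective rate, and the two summary-level group tests
# (Welch t, Pearson chi-square).

.pasi_regions <- c("h", "u", "t", "l")

#' Default PASI region weights
#'
#' Head 0.1, upper limbs 0.2, trunk 0.3, lower limbs 0.4; they sum to 1.
#' @return Named numeric vector.
#' @export
pasi_weights <- function() c(h = 0.1, u = 0.2, t = 0.3, l = 0.4)

#' One body region's lesion assessment
#'
#' @param region \code{"h"} (head), \code{"u"} (upper limbs), \code{"t"}
#'   (trunk) or \code{"l"} (lower limbs).
#' @param E erythema (spot colour) severity, integer 0..4.
#' @param I infiltration severity, integer 0..4.
#' @param D desquamation (scale) severity, integer 0..4.
#' @param P area score, integer 0..6 (see [area_score()]).
#' @return A \code{region_assessment}.
#' @export
region_assessment <- function(region, E, I, D, P) {
  region <- match.arg(region, .pasi_regions)
  chk <- function(x, hi, nm) {
    if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < 0L || x > hi)
      stop(nm, " must be an integer in 0..", hi)
    as.integer(x)
  }
  structure(list(region = region, E = chk(E, 4L, "E"), I = chk(I, 4L, "I"),
                 D = chk(D, 4L, "D"), P = chk(P, 6L, "P")),
            class = "region_assessment")
}

#' Area score from percent body-region involvement
#'
#' Standard PASI area bins: 0% scores 0, then (0,10) -> 1, [10,30) -> 2,
#' [30,50) -> 3, [50,70) -> 4, [70,90) -> 5, [90,100] -> 6.  The breaks are
#' configurable for variant conventions.
#'
#' @param lesion_area_percent percent of the region involved, in 0..100.
#' @param breaks upper-open bin edges between scores 1..6.
#' @return Integer score 0..6 (vectorized).
#' @export
area_score <- function(lesion_area_percent, breaks = c(10, 30, 50, 70, 90)) {
  p <- as.numeric(lesion_area_percent)
  if (any(is.na(p)) || any(p < 0) || any(p > 100))
    stop("lesion area percent must be in [0, 100]")
  if (length(breaks) != 5L || is.unsorted(breaks, strictly = TRUE))
    stop("`breaks` must be 5 strictly increasing edges")
  out <- 1L + rowSums(outer(p, breaks, `>=`))
  out[p == 0] <- 0L
  as.integer(out)
}

.as_assessment_df <- function(assessments) {
  if (inherits(assessments, "region_assessment"))
    assessments <- list(assessments)
  if (is.list(assessments) && !is.data.frame(assessments) &&
      all(vapply(assessments, inherits, logical(1L), "region_assessment"))) {
    assessments <- do.call(rbind, lapply(assessments, function(a)
      data.frame(region = a$region, E = a$E, I = a$I, D = a$D, P = a$P)))
  }
  if (!is.data.frame(assessments) ||
      !all(c("region", "E", "I", "D", "P") %in% names(assessments)))
    stop("assessments must have columns region, E, I, D, P")
  assessments
}

#' PASI score of one patient
#'
#' The weighted sum over the four body regions of
#' \code{(E + I + D) * P * weight}; with the default weights the score lies
#' in [0, 72].
#'
#' @param assessments a data frame with columns \code{region, E, I, D, P}
#'   covering each of h, u, t, l exactly once, or a list of
#'   [region_assessment()] objects.
#' @param weights region weights; must cover the four regions.
#' @return The PASI score.
#' @examples
#' pasi_score(data.frame(region = c("h", "u", "t", "l"),
#'                       E = 2, I = 3, D = 1, P = 4))
#' @export
pasi_score <- function(assessments, weights = pasi_weights()) {
  df <- .as_assessment_df(assessments)
  if (!setequal(df$region, .pasi_regions) || nrow(df) != 4L)
    stop("need exactly one assessment for each region h, u, t, l")
  if (!all(.pasi_regions %in% names(weights)))
    stop("weights must name regions h, u, t, l")
  for (col in c("E", "I", "D")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v != as.integer(v)) || any(v < 0) || any(v > 4))
      stop("invalid ", col, " score: must be integer in 0..4")
  }
  if (any(is.na(df$P)) || any(df$P != as.integer(df$P)) ||
      any(df$P < 0) || any(df$P > 6))
    stop("invalid P score: must be integer in 0..6")
  sum((df$E + df$I + df$D) * df$P * weights[df$region])
}

#' Before/after PASI pair
#' @param before,after PASI scores, each in [0, 72].
#' @return A \code{pasi_pair}.
#' @export
pasi_pair <- function(before, after) {
  for (x in c(before, after))
    if (!is.finite(x) || x < 0 || x > 72)
      stop("PASI scores must lie in [0, 72]")
  structure(list(before = as.numeric(before), after = as.numeric(after)),
            class = "pasi_pair")
}

.as_pair <- function(pair, after) {
  if (inherits(pair, "pasi_pair")) pair else pasi_pair(pair, after)
}

#' Absolute PASI reduction
#'
#' \code{before - after}; negative when the patient worsened.
#'
#' @param pair a [pasi_pair()], or the before score.
#' @param after the after score when \code{pair} is a bare number.
#' @return The score difference.
#' @export
delta_pasi <- function(pair, after = NULL) {
  p <- .as_pair(pair, after)
  p$before - p$after
}

#' Relative PASI reduction, in percent
#'
#' \code{100 * (before - after) / before}; the primary efficacy measure the
#' efficacy categories are cut from.
#'
#' @inheritParams delta_pasi
#' @return Percent reduction (unrounded).
#' @export
delta_pasi_percent <- function(pair, after = NULL) {
  p <- .as_pair(pair, after)
  if (p$before == 0)
    stop("undefined rate: PASI before treatment is 0")
  100 * (p$before - p$after) / p$before
}

#' Itching score on the four-level scale
#'
#' 0 none; 2 mild, daily life unaffected; 4 paroxysmal, needs medication;
#' 6 severe.
#'
#' @param score one of 0, 2, 4, 6.
#' @return The validated score.
#' @export
itching_score <- function(score) {
  if (length(score) != 1L || !score %in% c(0, 2, 4, 6))
    stop("itching score must be one of 0, 2, 4, 6")
  as.integer(score)
}

.efficacy_levels <- c("cured", "markedly_effective", "effective",
                      "ineffective")

#' Efficacy category from percent PASI reduction
#'
#' Closed-below cuts: cured at or above the first threshold, markedly
#' effective at or above the second, effective at or above the third,
#' ineffective below it.  Defaults follow the usual 90/60/30 convention for
#' lesion regression.
#'
#' @param delta_pasi_pct percent PASI reduction (vectorized).
#' @param thresholds strictly decreasing triple of percent cuts.
#' @return Factor with levels cured, markedly_effective, effective,
#'   ineffective.
#' @export
efficacy_category <- function(delta_pasi_pct, thresholds = c(90, 60, 30)) {
  if (length(thresholds) != 3L || is.unsorted(rev(thresholds),
                                              strictly = TRUE))
    stop("thresholds must be a strictly decreasing triple")
  idx <- 4L - rowSums(outer(as.numeric(delta_pasi_pct), thresholds, `>=`))
  factor(.efficacy_levels[idx], levels = .efficacy_levels)
}

#' Per-arm efficacy category counts
#'
#' @param cured,markedly_effective,effective,ineffective non-negative counts.
#' @return A \code{group_outcome} with the counts and their total \code{n}.
#' @export
group_outcome <- function(cured, markedly_effective, effective, ineffective) {
  counts <- c(cured = cured, markedly_effective = markedly_effective,
              effective = effective, ineffective = ineffective)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != as.integer(counts)))
    stop("category counts must be non-negative integers")
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  if (n == 0L) stop("group outcome needs at least one patient")
  structure(list(counts = counts, n = n), class = "group_outcome")
}

#' Round half away from zero
#'
#' Reporting-style rounding (5 rounds up), unlike [round()]'s round-half-even.
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Share of a count in a group, in percent
#' @param count numerator.
#' @param n denominator, > 0.
#' @param digits decimal places for half-up rounding; \code{NULL} for the
#'   unrounded value.
#' @return Percent.
#' @export
rate_percent <- function(count, n, digits = 2L) {
  if (n <= 0) stop("n must be positive")
  r <- 100 * count / n
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Total effective rate of a treatment arm
#'
#' The percentage of patients in the top three categories (cured + markedly
#' effective + effective) of the arm, reported half-up to \code{digits}
#' decimals.
#'
#' @param outcome a [group_outcome()].
#' @param digits decimal places (\code{NULL} for unrounded).
#' @return Percent of effective-or-better patients.
#' @examples
#' total_effective_rate(group_outcome(71, 213, 32, 40))  # 88.76
#' @export
total_effective_rate <- function(outcome, digits = 2L) {
  stopifnot(inherits(outcome, "group_outcome"))
  rate_percent(sum(outcome$counts[c("cured", "markedly_effective",
                                    "effective")]),
               outcome$n, digits)
}

#' Welch t test from group summaries
#'
#' Unequal-variance two-sample t test computed from means, SDs and sizes,
#' with Welch-Satterthwaite degrees of freedom and a two-sided p value.  Set
#' \code{pooled = TRUE} for the classic equal-variance Student test.
#'
#' @param mean1,sd1,n1 first group's mean, SD (> 0) and size (>= 2).
#' @param mean2,sd2,n2 second group's summary.
#' @param pooled use the pooled-variance Student form instead of Welch.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @examples
#' welch_t_from_summary(3.03, 1.01, 356, 3.71, 1.06, 356)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 pooled = FALSE) {
  if (any(!is.finite(c(mean1, sd1, n1, mean2, sd2, n2))))
    stop("summaries must be finite")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2 x k count table
#'
#' Plain Pearson chi-square without continuity correction (the 2 x k
#' contingency test used for category distributions); df = k - 1 for two
#' rows.
#'
#' @param counts numeric matrix of counts, 2 rows (groups) by k columns
#'   (categories), or anything coercible to one.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
chi_square_2xk <- function(counts) {
  m <- as.matrix(counts)
  if (any(is.na(m)) || any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in the contingency table")
  ht <- stats::chisq.test(m, correct = FALSE)
  if (any(ht$expected <= 0)) stop("expected counts must be positive")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

# ---- delimited-text interfaces ---------------------------------------------

#' Read per-patient region assessments from CSV
#'
#' Expected header: \code{patient_id, region, E, I, D, P, timepoint}.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "region", "E", "I", "D", "P", "timepoint")
  if (!all(need %in% names(df)))
    stop("assessments CSV needs columns: ", paste(need, collapse = ", "))
  if (!all(df$region %in% .pasi_regions))
    stop("region must be one of h, u, t, l")
  df
}

#' PASI per patient and timepoint
#'
#' @param assessments data frame from [read_assessments()].
#' @param weights region weights.
#' @return Data frame with \code{patient_id, timepoint, pasi}.
#' @export
pasi_table <- function(assessments, weights = pasi_weights()) {
  groups <- split(assessments,
                  list(assessments$patient_id, assessments$timepoint),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(patient_id = g$patient_id[1], timepoint = g$timepoint[1],
               pasi = pasi_score(g, weights))))
  rownames(out) <- NULL
  out[order(out$patient_id, out$timepoint), ]
}

#' Read per-arm efficacy outcome counts from CSV
#'
#' Expected header:
#' \code{arm, cured, markedly_effective, effective, ineffective}.
#'
#' @param path CSV file.
#' @return Named list of [group_outcome()] objects, one per arm.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("arm", "cured", "markedly_effective", "effective", "ineffective")
  if (!all(need %in% names(df)))
    stop("outcomes CSV needs columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    group_outcome(df$cured[i], df$markedly_effective[i], df$effective[i],
                  df$ineffective[i]))
  names(out) <- df$arm
  out
}

#' Efficacy comparison across arms
#'
#' Per-arm total effective rates plus Pearson chi-square tests on the full
#' 2 x 4 category table and on the collapsed effective-vs-ineffective 2 x 2
#' table (first two arms).
#'
#' @param outcomes named list of [group_outcome()]s (at least two arms).
#' @param digits rounding for the reported rates.
#' @return List with \code{rates}, \code{chi_square_categories},
#'   \code{chi_square_effective}.
#' @export
efficacy_report <- function(outcomes, digits = 2L) {
  if (length(outcomes) < 2L) stop("need at least two arms")
  rates <- vapply(outcomes, total_effective_rate, numeric(1L),
                  digits = digits)
  tab4 <- do.call(rbind, lapply(outcomes[1:2], `[[`, "counts"))
  eff <- cbind(effective = rowSums(tab4[, 1:3, drop = FALSE]),
               ineffective = tab4[, 4])
  list(rates = rates,
       chi_square_categories = chi_square_2xk(tab4),
       chi_square_effective = chi_square_2xk(eff))
}
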