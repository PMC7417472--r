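#' Relative trait value under stress
#'
#' The salt-tolerance screening traits are relative values: the measurement
#' under the salt treatment divided by the measurement under the control
#' condition (RSL = relative shoot length, RRN = relative root number,
#' RRL = relative root length). A value of 0 means growth stopped entirely
#' under stress; values near 1 mean the line was unaffected.
#'
#' @param treatment Non-negative measurement(s) under salt treatment.
#' @param control Strictly positive measurement(s) under control conditions.
#' @return `treatment / control`, vectorized.
#' @export
#' @examples
#' relative_value(5, 10)   # 0.5
#' relative_value(0, 10)   # 0: growth stopped under stress
relative_value <- function(treatment, control) {
  if (any(!is.finite(treatment)) || any(!is.finite(control)))
    abort("treatment and control must be finite")
  if (any(treatment < 0) || any(control < 0))
    abort("negative measurements are not valid phenotype values")
  if (any(control == 0))
    abort("undefined ratio: control value of 0 (flag and exclude the record)")
  treatment / control
}

#' Relative traits for a phenotype table
#'
#' Table-level wrapper around [relative_value()]: maps raw trait labels to
#' their relative counterparts (`SL -> RSL`, `RN -> RRN`, `RL -> RRL`) and
#' drops records whose control value is 0 (undefined ratio) with a warning
#' stating how many were excluded.
#'
#' @param phenotypes Data frame with columns `line_id`, `trait`,
#'   `control_value`, `treatment_value`.
#' @return Tibble `line_id`, `trait` (relative label), `value`.
#' @export
relative_traits <- function(phenotypes) {
  stopifnot(all(c("line_id", "trait", "control_value", "treatment_value") %in%
                  names(phenotypes)))
  map <- c(SL = "RSL", RN = "RRN", RL = "RRL")
  bad <- phenotypes$control_value == 0
  if (any(bad))
    warn(sprintf("%d record(s) with control value 0 excluded (undefined ratio)",
                 sum(bad)))
  keep <- phenotypes[!bad, , drop = FALSE]
  tibble(
    line_id = keep$line_id,
    trait = unname(ifelse(keep$trait %in% names(map), map[keep$trait], keep$trait)),
    value = relative_value(keep$treatment_value, keep$control_value)
  )
}

#' Distribution diagnostics for a trait
#'
#' Computes bias-corrected sample skewness and excess kurtosis (normal = 0)
#' and flags the trait as suitable for QTL mapping when both absolute values
#' are below 1 — the usual rule of thumb for treating a segregating trait as
#' approximately normal. A Shapiro-Wilk test supplies a formal normality
#' flag for sample sizes up to 5000.
#'
#' @param values Numeric trait values, `n >= 8`.
#' @param trait Optional trait label carried into the output.
#' @return One-row tibble: `trait`, `n`, `skewness`, `kurtosis`,
#'   `normality_ok`, `qtl_suitable`, `reason`.
#' @export
#' @examples
#' diagnose_distribution(rnorm(200), "RSL")
diagnose_distribution <- function(values, trait = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) abort("need at least 8 values for distribution diagnostics")

  if (length(unique(values)) == 1L) {
    return(tibble(trait = trait, n = n, skewness = NA_real_, kurtosis = NA_real_,
                  normality_ok = NA, qtl_suitable = FALSE,
                  reason = "constant input: moments undefined"))
  }
  sk <- e1071::skewness(values, type = 2)    # bias-corrected (SAS/Excel)
  ku <- e1071::kurtosis(values, type = 2)    # bias-corrected excess kurtosis
  norm_ok <- if (n <= 5000) shapiro.test(values)$p.value > 0.05 else NA
  suitable <- is.finite(sk) && is.finite(ku) && abs(sk) < 1 && abs(ku) < 1
  tibble(trait = trait, n = n, skewness = sk, kurtosis = ku,
         normality_ok = norm_ok, qtl_suitable = suitable,
         reason = if (suitable) NA_character_ else "|skewness| or |kurtosis| >= 1")
}

#' Compare trait values between the two pools
#'
#' Summarises each pool (median and quartiles) and tests for a location
#' difference with a two-sided Wilcoxon rank-sum test; the direction flag
#' states which pool has the larger median. The rank-sum test is preferred
#' over a t test because relative traits such as RRN/RRL are typically
#' zero-inflated.
#'
#' @param values_t,values_s Trait values in the tolerant and sensitive pool.
#' @return One-row tibble: `n_t`, `n_s`, `median_t`, `q1_t`, `q3_t`,
#'   `median_s`, `q1_s`, `q3_s`, `p_value`, `direction`
#'   (`"T>S"`, `"S>T"` or `"none"`).
#' @export
#' @examples
#' compare_pools(c(3, 4, 5), c(1, 1, 2))
compare_pools <- function(values_t, values_s) {
  if (length(values_t) == 0 || length(values_s) == 0)
    abort("both pools must be non-empty")
  q_t <- quantile(values_t, c(0.25, 0.5, 0.75), names = FALSE)
  q_s <- quantile(values_s, c(0.25, 0.5, 0.75), names = FALSE)
  p <- if (length(values_t) < 3 || length(values_s) < 3) {
    warn("fewer than 3 values in a pool: rank-sum test skipped")
    NA_real_
  } else {
    suppressWarnings(wilcox.test(values_t, values_s, exact = FALSE))$p.value
  }
  direction <- if (q_t[2] > q_s[2]) "T>S" else if (q_t[2] < q_s[2]) "S>T" else "none"
  tibble(n_t = length(values_t), n_s = length(values_s),
         median_t = q_t[2], q1_t = q_t[1], q3_t = q_t[3],
         median_s = q_s[2], q1_s = q_s[1], q3_s = q_s[3],
         p_value = p, direction = direction)
}
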