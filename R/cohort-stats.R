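as_cohort <- function(table) {
  need <- c("fish_id", "genotype", "value")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop_spec("cohort table must contain columns ",
              paste(need, collapse = ", "))
  }
  table$genotype <- factor(as.character(table$genotype),
                           levels = c("WT", "mutant"))
  if (anyNA(table$genotype)) {
    stop_spec("genotype must be 'WT' or 'mutant'")
  }
  table
}

#' Select wild-type controls matching the mutant body size
#'
#' Keeps wild-type fish whose body length lies within `tolerance` (default
#' 10%) of the mean mutant body length, so intraocular changes are
#' isolated from globally altered body dimensions.  Filtering is at the
#' fish level: both eyes of a fish are kept or dropped together.
#'
#' @param table a cohort table with columns `fish_id`, `genotype`,
#'   `body_length_mm`, `value`.
#' @param tolerance half-width of the acceptance band as a fraction of the
#'   mean mutant body length (default 0.10).
#' @return The table with out-of-band wild-type fish removed; attribute
#'   `n_dropped_fish` records how many were excluded.
#' @examples
#' co <- generate_cohort(cohort_spec())
#' nrow(size_match_controls(co))
#' @export
size_match_controls <- function(table, tolerance = 0.10) {
  table <- as_cohort(table)
  if (!"body_length_mm" %in% names(table)) {
    stop_spec("cohort table must contain 'body_length_mm'")
  }
  mut <- table[table$genotype == "mutant", ]
  if (nrow(mut) == 0L) stop_spec("mutant group is empty")
  centre <- mean(tapply(mut$body_length_mm, mut$fish_id, mean))
  lo <- (1 - tolerance) * centre
  hi <- (1 + tolerance) * centre
  wt_len <- tapply(table$body_length_mm[table$genotype == "WT"],
                   droplevels(factor(table$fish_id[table$genotype == "WT"])),
                   mean)
  keep_fish <- names(wt_len)[wt_len >= lo & wt_len <= hi]
  out <- table[table$genotype == "mutant" | table$fish_id %in% keep_fish, ]
  attr(out, "n_dropped_fish") <- length(wt_len) - length(keep_fish)
  rownames(out) <- NULL
  out
}

#' Fit the random-intercept linear mixed model for paired eyes
#'
#' Fits `value ~ genotype + (1 | fish_id)` by REML: genotype (wild type or
#' mutant) is a fixed factor and fish a random factor, so the correlation
#' between the two eyes of one fish is absorbed by the per-fish random
#' intercept.  The genotype fixed effect is reported with its standard
#' error and a Wald p-value (normal reference).
#'
#' @param table a cohort table (`fish_id`, `genotype`, `value`).
#' @param outcome optional outcome name; when the table has an `outcome`
#'   column it is filtered to this value.
#' @return A list of class `lmm_fit`: `effect` (mutant minus WT), `se`,
#'   `p_value`, `intercept`, `sd_fish` (random-intercept SD),
#'   `sd_residual`, `n_fish` (per genotype), `n_eyes`, `singular`,
#'   `converged`.
#' @examples
#' fit_random_intercept_lmm(generate_cohort(cohort_spec(seed = 2)))$effect
#' @export
fit_random_intercept_lmm <- function(table, outcome = NULL) {
  tab <- as_cohort(table)
  if (!is.null(outcome) && "outcome" %in% names(tab)) {
    tab <- tab[tab$outcome == outcome, ]
  }
  fish_geno <- unique(tab[c("fish_id", "genotype")])
  n_fish <- c(WT = sum(fish_geno$genotype == "WT"),
              mutant = sum(fish_geno$genotype == "mutant"))
  if (any(n_fish < 2L)) {
    stop_spec("need >= 2 fish in each genotype group")
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ genotype + (1 | fish_id), data = tab, REML = TRUE)))
  co <- summary(fit)$coefficients
  beta1 <- co["genotypemutant", "Estimate"]
  se <- co["genotypemutant", "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(effect = unname(beta1), se = unname(se),
                 p_value = 2 * stats::pnorm(-abs(beta1 / se)),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 sd_fish = vc$sdcor[vc$grp == "fish_id"],
                 sd_residual = vc$sdcor[vc$grp == "Residual"],
                 n_fish = n_fish, n_eyes = nrow(tab),
                 singular = lme4::isSingular(fit),
                 converged = length(fit@optinfo$conv$lme4) == 0L),
            class = "lmm_fit")
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Welch's F test for a difference in means across two or more groups with
#' unequal variances, with the Welch-Satterthwaite approximation for the
#' denominator degrees of freedom.  For two groups the statistic equals
#' the square of Welch's t.
#'
#' @param groups a list of numeric vectors (one per group, each with n >=
#'   2 and positive variance), or a single data.frame with columns `value`
#'   and `group`.
#' @return A list of class `welch_anova_result`: `f`, `df1`, `df2`,
#'   `p_value`, `n` (per-group sizes).
#' @examples
#' welch_anova(list(rnorm(10), rnorm(10, 1)))$p_value
#' @export
welch_anova <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2L) stop_spec("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop_spec("each group needs n >= 2")
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop_spec("a group has zero variance: Welch's ANOVA undefined")
  }
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(seq_along(groups), sizes))
  ow <- stats::oneway.test(value ~ group, var.equal = FALSE)
  structure(list(f = unname(ow$statistic), df1 = unname(ow$parameter[1L]),
                 df2 = unname(ow$parameter[2L]),
                 p_value = unname(ow$p.value), n = unname(sizes)),
            class = "welch_anova_result")
}

#' Cross-sectional mixed-model report over ages
#'
#' Ages (time points) are analyzed separately rather than longitudinally:
#' per age label the wild-type controls are size-matched to the mutants
#' and the random-intercept mixed model is fitted.  Failures at one age
#' are flagged without affecting the others.
#'
#' @param table a cohort table with an `age` column.
#' @param outcome optional outcome filter (see
#'   [fit_random_intercept_lmm()]).
#' @param size_match whether to apply [size_match_controls()] per age
#'   (default TRUE; requires `body_length_mm`).
#' @param tolerance size-matching tolerance.
#' @return A data.frame with one row per age: `age`, `effect`, `se`,
#'   `p_value`, `n_fish_wt`, `n_fish_mut`, `error` (NA or the failure
#'   message).
#' @export
crosssectional_report <- function(table, outcome = NULL, size_match = TRUE,
                                  tolerance = 0.10) {
  table <- as_cohort(table)
  if (!"age" %in% names(table)) stop_spec("cohort table must contain 'age'")
  ages <- unique(table$age)
  rows <- lapply(ages, function(a) {
    sub <- table[table$age == a, ]
    res <- tryCatch({
      if (size_match) sub <- size_match_controls(sub, tolerance)
      fit <- fit_random_intercept_lmm(sub, outcome)
      data.frame(age = a, effect = fit$effect, se = fit$se,
                 p_value = fit$p_value, n_fish_wt = fit$n_fish[1L],
                 n_fish_mut = fit$n_fish[2L], error = NA_character_)
    }, error = function(e) {
      data.frame(age = a, effect = NA_real_, se = NA_real_,
                 p_value = NA_real_, n_fish_wt = NA_integer_,
                 n_fish_mut = NA_integer_, error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
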