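#' Simulate a cohort demographics table
#'
#' One row per subject with categorical variables (sex, handedness, site,
#' income bracket, parental education, ethnicity, anesthesia exposure) and
#' numeric variables (age in years, retained low-motion frames). A fraction
#' of subjects belong to multi-member families (siblings/twins) who share
#' household-level variables; family ids partition subjects.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param family_fraction Fraction of subjects belonging to families of
#'   size 2-3.
#' @param n_sites Number of acquisition sites.
#' @return A data.frame with `subject_id`, `family_id`, categorical and
#'   numeric covariates.
#' @export
simulate_demographics <- function(n_subjects, seed = 1L,
                                  family_fraction = 0.2, n_sites = 4L) {
  withr::with_seed(seed, {
    # build family blocks first
    fam_sizes <- integer(0)
    remaining <- round(n_subjects * family_fraction)
    while (remaining >= 2L) {
      s <- sample(2:3, 1L)
      s <- min(s, remaining)
      if (s < 2L) break
      fam_sizes <- c(fam_sizes, s)
      remaining <- remaining - s
    }
    n_single <- n_subjects - sum(fam_sizes)
    fam_id <- c(rep(seq_along(fam_sizes), fam_sizes),
                seq_len(n_single) + length(fam_sizes))
    n_fam <- max(fam_id)
    # household-level covariates shared within family
    site <- sample.int(n_sites, n_fam, replace = TRUE)[fam_id]
    income <- sample(c("low", "mid", "high"), n_fam, replace = TRUE,
                     prob = c(0.25, 0.45, 0.30))[fam_id]
    education <- sample(c("hs", "college", "postgrad"), n_fam,
                        replace = TRUE, prob = c(0.3, 0.5, 0.2))[fam_id]
    ethnicity <- sample(c("white", "black", "hispanic", "asian", "other"),
                        n_fam, replace = TRUE,
                        prob = c(0.56, 0.13, 0.19, 0.02, 0.10))[fam_id]
    data.frame(
      subject_id = sprintf("sub%04d", seq_len(n_subjects)),
      family_id = fam_id,
      sex = sample(c("F", "M"), n_subjects, replace = TRUE),
      handedness = sample(c("R", "L", "A"), n_subjects, replace = TRUE,
                          prob = c(0.81, 0.07, 0.12)),
      site = factor(site),
      income = income,
      education = education,
      ethnicity = ethnicity,
      anesthesia = sample(c("no", "yes"), n_subjects, replace = TRUE,
                          prob = c(0.85, 0.15)),
      age = rnorm(n_subjects, 9.9, 0.62),
      retained_frames = round(rnorm(n_subjects, 1141, 245)),
      stringsAsFactors = FALSE
    )
  })
}

#' Chi-square test of independence on a contingency table
#'
#' Classical Pearson chi-square without continuity correction, with the
#' p-value from the chi-square distribution at (r-1)(c-1) degrees of
#' freedom. Used for cohort-balance tests on categorical demographics.
#'
#' @param counts Matrix of nonnegative integer counts, >= 2 rows and
#'   columns, no zero marginal row/column.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' contingency_chi2(rbind(c(50, 50), c(50, 50)))$p_value # 1
#' @export
contingency_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("counts must have at least 2 rows and 2 columns")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal row/column")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Two-sample t-test from summary statistics
#'
#' Student's pooled-variance form by default (`welch = TRUE` switches to the
#' Welch unequal-variance form), for use when only group means, standard
#' deviations and sizes are available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch form instead of pooled variance.
#' @return List with `t`, `df`, `p_value`.
#' @export
summary_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 <= 1 || n2 <= 1) stop("each group needs n > 1")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be nonnegative")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# balance score of a candidate split: sum of chi-square statistics over
# categorical variables plus squared standardized mean differences over
# numeric variables (lower is better matched)
split_balance_score <- function(table, half, categorical, numeric) {
  score <- 0
  for (v in categorical) {
    ct <- table(table[[v]], half)
    ct <- ct[rowSums(ct) > 0, , drop = FALSE]
    if (nrow(ct) < 2 || ncol(ct) < 2 || any(colSums(ct) == 0)) next
    e <- outer(rowSums(ct), colSums(ct)) / sum(ct)
    score <- score + sum((ct - e)^2 / e)
  }
  for (v in numeric) {
    x1 <- table[[v]][half == 1L]
    x2 <- table[[v]][half == 2L]
    sp <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
    if (is.na(sp) || sp == 0) next
    score <- score + ((mean(x1) - mean(x2)) / sp)^2
  }
  score
}

#' Family-respecting matched split of a demographics table
#'
#' Divides subjects into two disjoint, exhaustive halves such that all
#' members of a family land in the same half and the halves contain equal
#' (within one) numbers of singleton subjects and of family groups. Among
#' `n_candidates` randomized family-intact assignments, the split minimizing
#' the summed balance statistics (chi-square for categorical variables,
#' squared standardized mean difference for numeric variables) is kept.
#'
#' @param table Demographics data.frame with a `family_id` column.
#' @param categorical Character vector of categorical variable names;
#'   defaults to all character/factor columns except ids.
#' @param numeric Character vector of numeric variable names; defaults to
#'   all numeric columns except `family_id`.
#' @param n_candidates Number of randomized splits scored.
#' @param seed Integer seed.
#' @return List with `discovery` and `replication` (row index vectors),
#'   `score`, and `balance` (per-variable test results on the chosen split).
#' @export
matched_split <- function(table, categorical = NULL, numeric = NULL,
                          n_candidates = 1000L, seed = 1L) {
  if (nrow(table) == 0) stop("table must be nonempty")
  if (!"family_id" %in% names(table)) stop("table needs a family_id column")
  id_cols <- c("subject_id", "family_id")
  if (is.null(categorical)) {
    categorical <- names(table)[vapply(table, function(x)
      is.character(x) || is.factor(x), logical(1))]
    categorical <- setdiff(categorical, id_cols)
  }
  if (is.null(numeric)) {
    numeric <- names(table)[vapply(table, is.numeric, logical(1))]
    numeric <- setdiff(numeric, id_cols)
  }

  fam <- split(seq_len(nrow(table)), table$family_id)
  sizes <- lengths(fam)
  if (any(sizes > nrow(table) / 2))
    stop("a single family is larger than half the sample")
  singles <- fam[sizes == 1L]
  groups <- fam[sizes > 1L]

  assign_half <- function() {
    half <- integer(nrow(table))
    for (units in list(singles, groups)) {
      if (length(units) == 0L) next
      ord <- sample(length(units))
      h <- rep(c(1L, 2L), length.out = length(units))
      for (i in seq_along(units))
        half[units[[ord[i]]]] <- h[i]
    }
    half
  }

  withr::with_seed(seed, {
    best <- NULL
    best_score <- Inf
    for (cand in seq_len(n_candidates)) {
      half <- assign_half()
      s <- split_balance_score(table, half, categorical, numeric)
      if (s < best_score) {
        best_score <- s
        best <- half
      }
    }
  })

  balance <- list()
  for (v in categorical) {
    ct <- table(table[[v]], best)
    ct <- ct[rowSums(ct) > 0, , drop = FALSE]
    if (nrow(ct) >= 2 && ncol(ct) >= 2 && all(colSums(ct) > 0))
      balance[[v]] <- contingency_chi2(unclass(ct))
  }
  for (v in numeric) {
    x1 <- table[[v]][best == 1L]; x2 <- table[[v]][best == 2L]
    balance[[v]] <- summary_t_test(mean(x1), sd(x1), length(x1),
                                   mean(x2), sd(x2), length(x2))
  }

  list(discovery = which(best == 1L), replication = which(best == 2L),
       score = best_score, balance = balance)
}
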