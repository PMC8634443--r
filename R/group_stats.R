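# Group-level statistics: summary-statistic tests, ANCOVA, post-hoc pooled
# t-tests with Bonferroni correction, clinical correlations with BH-FDR.

#' Construct a group design
#'
#' Subject table for a three-group case-control design. Clinical fields
#' (disease duration in months, PANSS total, MOAS) may be missing for
#' healthy controls only.
#'
#' @param subject_id Character vector of subject ids.
#' @param group Group labels; coerced to a factor (default level order
#'   \code{HC}, \code{NSZ}, \code{VSZ} when those labels are used).
#' @param duration,PANSS,MOAS Optional numeric clinical measures.
#' @return Data frame of class \code{group_design}.
#' @export
group_design <- function(subject_id, group, duration = NULL, PANSS = NULL,
                         MOAS = NULL) {
  n <- length(subject_id)
  if (anyDuplicated(subject_id)) stopf("duplicate subject ids")
  lv <- if (all(unique(group) %in% c("HC", "NSZ", "VSZ")))
    intersect(c("HC", "NSZ", "VSZ"), unique(group)) else unique(group)
  group <- factor(group, levels = lv)
  if (any(table(group) == 0L)) stopf("empty group")
  df <- data.frame(subject_id = as.character(subject_id), group = group,
                   duration = duration %||% rep(NA_real_, n),
                   PANSS = PANSS %||% rep(NA_real_, n),
                   MOAS = MOAS %||% rep(NA_real_, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("group_design", "data.frame")
  df
}

#' Read a group design from a subjects TSV
#'
#' Expected columns: \code{subject_id}, \code{group}, and optionally
#' \code{duration_months}, \code{PANSS_total}, \code{MOAS}.
#'
#' @param path Path to the TSV file.
#' @return A \code{\link{group_design}}.
#' @export
read_group_design <- function(path) {
  df <- read_tsv(path)
  group_design(df$subject_id, df$group,
               duration = df$duration_months,
               PANSS = df$PANSS_total, MOAS = df$MOAS)
}

#' Write a group design to a subjects TSV
#'
#' @param design A \code{\link{group_design}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_group_design <- function(design, path) {
  out <- data.frame(subject_id = design$subject_id,
                    group = as.character(design$group),
                    duration_months = design$duration,
                    PANSS_total = design$PANSS, MOAS = design$MOAS)
  write_tsv(out, path)
}

#' Packaged demographic and clinical summary table
#'
#' Group means, SDs and sizes for age, education, illness duration, PANSS
#' total and MOAS in the three-group design (HC / NSZ / VSZ) that the
#' summary-statistic tests reproduce.
#'
#' @return Data frame with columns \code{variable}, \code{statistic},
#'   \code{HC}, \code{NSZ}, \code{VSZ}.
#' @export
demographics_table <- function() {
  read_tsv(system.file("extdata", "study_demographics.tsv",
                       package = "imcn", mustWork = TRUE))
}

stat_result <- function(test, comparison, statistic, df, p_raw,
                        p_adj = p_raw, method = "none", direction = NA_real_) {
  data.frame(test = test, comparison = comparison, statistic = statistic,
             df = I(list(df)), p_raw = p_raw, p_adj = p_adj,
             method = method, direction = direction,
             stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's t with \code{df = n1 + n2 - 2} reconstructed from group means,
#' SDs and sizes; two-sided p-value.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @param labels Length-2 comparison labels.
#' @return One-row \code{stat_result} data frame.
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  labels = c("group1", "group2")) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0 && mean1 != mean2)
    stopf("zero pooled variance with unequal means")
  tval <- if (sp2 == 0) 0 else
    (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  stat_result("pooled_t", paste(labels, collapse = " vs "), tval, df, p,
              direction = sign(mean2 - mean1))
}

#' One-way ANOVA F from summary statistics
#'
#' Between/within sums of squares reconstructed from per-group means, SDs
#' and sizes; \code{df = (G - 1, N - G)}.
#'
#' @param means,sds,ns Per-group summary vectors (equal length, >= 2 groups).
#' @return One-row \code{stat_result} data frame.
#' @export
anova_from_summary <- function(means, sds, ns) {
  G <- length(means)
  stopifnot(G >= 2, length(sds) == G, length(ns) == G, all(ns >= 2))
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0 && ssb > 0) stopf("degenerate within-group variance")
  Fval <- if (ssb == 0) 0 else (ssb / (G - 1)) / (ssw / (N - G))
  p <- pf(Fval, G - 1, N - G, lower.tail = FALSE)
  stat_result("oneway_F", paste(G, "groups"), Fval, c(G - 1, N - G), p)
}

# Partial-F engine shared by ancova() and voxelwise_anova(): Y is a matrix
# (units x subjects); returns F, p and the df pair for the group factor
# adjusted for covariates.
partial_f_engine <- function(Y, group, covariates) {
  N <- ncol(Y)
  G <- nlevels(group)
  C <- if (is.null(covariates)) 0L else ncol(covariates)
  X_red <- cbind(rep(1, N), covariates)
  X_full <- cbind(X_red, model.matrix(~group)[, -1, drop = FALSE])
  if (qr(X_full)$rank < ncol(X_full)) stopf("rank-deficient design matrix")
  df1 <- G - 1
  df2 <- N - G - C
  if (df2 <= 0) stopf("no residual degrees of freedom (N=%d, G=%d, C=%d)",
                      N, G, C)
  rss <- function(X) {
    Q <- qr.Q(qr(X))
    E <- Y - (Y %*% Q) %*% t(Q)
    rowSums(E * E)
  }
  rss_f <- rss(X_full)
  rss_r <- rss(X_red)
  ssb <- pmax(rss_r - rss_f, 0)
  scale <- rowSums(Y * Y) + 1
  Fv <- numeric(nrow(Y))
  degenerate <- rss_f <= scale * 1e-20
  Fv[!degenerate] <- (ssb[!degenerate] / df1) / (rss_f[!degenerate] / df2)
  Fv[degenerate & ssb > scale * 1e-20] <- Inf
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df = c(df1, df2))
}

# Apply the covariate policy: returns list(covariates matrix or NULL,
# keep = logical subject filter).
resolve_covariates <- function(design, covariate_names,
                               na_action = c("drop", "error", "impute")) {
  na_action <- match.arg(na_action)
  if (!length(covariate_names)) return(list(covariates = NULL, dropped = FALSE))
  X <- as.matrix(design[, covariate_names, drop = FALSE])
  if (!any(is.na(X))) return(list(covariates = X, dropped = FALSE))
  if (na_action == "error") {
    bad <- design$subject_id[!complete.cases(X)]
    stopf("covariate missing for subject(s): %s", paste(bad, collapse = ", "))
  }
  if (na_action == "impute") {
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    return(list(covariates = X, dropped = FALSE))
  }
  message(sprintf(
    "covariate(s) %s undefined for %d subject(s); dropped from the model",
    paste(covariate_names, collapse = ", "), sum(!complete.cases(X))))
  list(covariates = NULL, dropped = TRUE)
}

#' ANCOVA: group F-test adjusted for covariates
#'
#' Partial F comparing the model \code{intercept + covariates + group} to
#' the covariate-only model, with \code{df = (G - 1, N - G - C)}. With an
#' empty covariate list this reduces to one-way ANOVA. Covariates undefined
#' for some subjects are handled by \code{na_action}: \code{"drop"} removes
#' the covariates from the model (the default, suited to designs where
#' clinical covariates are undefined for controls), \code{"impute"}
#' mean-imputes them, \code{"error"} aborts naming the subjects.
#'
#' @param values Numeric per-subject measure.
#' @param design A \code{\link{group_design}}.
#' @param covariates Character vector of design column names.
#' @param na_action Covariate missingness policy.
#' @return One-row \code{stat_result} data frame.
#' @export
ancova <- function(values, design, covariates = character(),
                   na_action = "drop") {
  stopifnot(length(values) == nrow(design))
  rc <- resolve_covariates(design, covariates, na_action)
  res <- partial_f_engine(matrix(values, nrow = 1), design$group,
                          rc$covariates)
  stat_result("ancova_F",
              paste(levels(design$group), collapse = "/"),
              res$F, res$df, res$p,
              method = if (is.null(rc$covariates)) "unadjusted"
                       else paste("adjusted:", paste(covariates, collapse = "+")))
}

#' Pairwise pooled t-tests with Bonferroni correction
#'
#' All group pairs are compared with pooled-variance two-sample t-tests;
#' each raw p-value is multiplied by the number of pairs and capped at 1.
#'
#' @param values Numeric per-subject measure.
#' @param design A \code{\link{group_design}}.
#' @param var_equal Use the pooled-variance (Student) test; \code{FALSE}
#'   gives Welch.
#' @return Data frame with one row per pair: statistic, df, raw and
#'   Bonferroni-adjusted p, and the direction of the difference
#'   (sign of mean2 - mean1).
#' @export
posthoc_bonferroni <- function(values, design, var_equal = TRUE) {
  stopifnot(length(values) == nrow(design))
  gl <- levels(design$group)
  if (length(gl) < 2) stopf("need at least two groups")
  if (any(table(design$group) < 2)) stopf("a group has fewer than 2 subjects")
  pairs <- utils::combn(gl, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- values[design$group == pairs[1, k]]
    b <- values[design$group == pairs[2, k]]
    if (var_equal) {
      r <- pooled_t_from_summary(mean(a), sd(a), length(a),
                                 mean(b), sd(b), length(b),
                                 labels = pairs[, k])
    } else {
      tt <- stats::t.test(b, a, var.equal = FALSE)
      r <- stat_result("welch_t", paste(pairs[, k], collapse = " vs "),
                       unname(tt$statistic), unname(tt$parameter),
                       tt$p.value, direction = sign(mean(b) - mean(a)))
    }
    r
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * m)
  out$method <- "bonferroni"
  out
}

#' Clinical correlation analysis with BH-FDR correction
#'
#' Correlates every (measure, score) column pair over subjects present in
#' both tables, using Pearson's r by default. All pairs in one call form a
#' single Benjamini-Hochberg family. Pairs with a constant vector or fewer
#' than 3 complete observations are flagged (\code{NA} statistics) and
#' excluded from the FDR family.
#'
#' @param measures Data frame: \code{subject_id} plus measure columns.
#' @param scores Data frame: \code{subject_id} plus clinical score columns.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param q FDR level for the significance flag.
#' @return Data frame with one row per pair: \code{measure}, \code{score},
#'   \code{n}, \code{r}, \code{p_raw}, \code{p_adj}, \code{significant}.
#' @export
clinical_correlations <- function(measures, scores, method = "pearson",
                                  q = 0.05) {
  stopifnot("subject_id" %in% names(measures),
            "subject_id" %in% names(scores))
  merged <- merge(measures, scores, by = "subject_id")
  mcols <- setdiff(names(measures), "subject_id")
  scols <- setdiff(names(scores), "subject_id")
  rows <- list()
  for (mc in mcols) for (sc in scols) {
    x <- merged[[mc]]; y <- merged[[sc]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        measure = mc, score = sc, n = n, r = NA_real_, p_raw = NA_real_)
      next
    }
    ct <- cor.test(x[ok], y[ok], method = method, exact = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = mc, score = sc, n = n, r = unname(ct$estimate),
      p_raw = ct$p.value)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  valid <- !is.na(out$p_raw)
  out$p_adj[valid] <- p.adjust(out$p_raw[valid], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj <= q
  out
}

#' Benjamini-Hochberg step-up procedure
#'
#' @param p_values Vector of p-values in [0, 1].
#' @param q FDR level.
#' @return List with logical \code{reject} and numeric \code{p_adj}
#'   (monotone BH-adjusted p-values).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) stopf("empty p-value vector")
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p_adj <- p.adjust(p_values, method = "BH")
  list(reject = !is.na(p_adj) & p_adj <= q, p_adj = p_adj)
}
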